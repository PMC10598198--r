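#' Simulate one closed-loop session for a synthetic agent
#'
#' Runs the full trial loop on a session schedule: quiz feedback is
#' drawn per trial, the mood trace integrates the feedbacks, ratings are
#' z-scored within the session (mood enters the agent's choice rule on
#' that analysis-time scale), and every trial presents one offer drawn
#' by the requested sampler. With `sampler = "otg"` the offer comes from
#' the per-cost-type indifference model, which is refitted on that
#' agent's own past choices after every trial -- the adaptive loop the
#' package exists to study. With `"grid"` or `"random"` the offers come
#' from a pre-committed queue (supply `offer_queue` to spread one grid
#' over several sessions). Response times decrease with the decision-
#' value advantage of the chosen option, with multiplicative log-normal
#' noise.
#'
#' All randomness uses the current RNG state; seed with `set.seed()`
#' for an exactly reproducible session.
#'
#' @param agent An [agent_profile()].
#' @param schedule A [make_session_schedule()] tibble.
#' @param sampler `"otg"`, `"grid"` or `"random"`.
#' @param otg_cfg An [otg_config()] (OTG sampler only).
#' @param grid An `otg_grid`.
#' @param offer_queue Optional named list (per cost type) of [offers()]
#'   tibbles consumed in order (grid/random samplers); defaults to a
#'   fresh draw sized to this session.
#' @param otg_state Optional OTG state to resume from (as produced in
#'   the `otg_state` attribute of a previous call).
#' @return A tibble of trial records: schedule columns plus `correct`,
#'   `feedback`, `mood_raw`, `mood_z`, offer columns, `dv`, `p_costly`,
#'   `choice`, `rt`. For OTG runs, the final per-cost-type state is
#'   attached as attribute `otg_state`.
#' @export
#' @examples
#' set.seed(7)
#' agent <- sample_agent()
#' trials <- simulate_session(agent, make_session_schedule(seed = 7))
#' dplyr::count(trials, cost_type, choice)
simulate_session <- function(agent, schedule, sampler = c("otg", "grid",
                                                          "random"),
                             otg_cfg = otg_config(), grid = build_grids(),
                             offer_queue = NULL, otg_state = NULL) {
  sampler <- match.arg(sampler)
  n <- nrow(schedule)
  slots <- simulate_quiz_feedback(schedule)
  mood_raw <- simulate_mood_trace(slots$feedback, agent$mood_params)
  mood_z <- as.numeric(scale(mood_raw))

  types <- cost_types()
  if (sampler == "otg") {
    if (is.null(otg_state)) {
      otg_state <- purrr::map(
        stats::setNames(types, types),
        ~ list(model = otg_prior_model(otg_cfg),
               history = offers(character(0), numeric(0), numeric(0))[0, ])
      )
    }
  } else if (is.null(offer_queue)) {
    per_type <- table(schedule$cost_type)
    offer_queue <- purrr::imap(as.list(per_type), function(m, ct) {
      if (sampler == "grid") {
        sizes <- c(9, 16, 25, 36, 64)
        baseline_sampler("grid", min(sizes[sizes >= m]), grid, ct)
      } else {
        baseline_sampler("random", m, grid, ct)
      }
    })
  }
  queue_pos <- stats::setNames(rep(1L, length(types)), types)

  rows <- vector("list", n)
  for (t in seq_len(n)) {
    ct <- schedule$cost_type[t]
    if (sampler == "otg") {
      map <- build_indifference_map(otg_state[[ct]]$model, grid)
      offer <- sample_next_offer(map, ct)
    } else {
      offer <- offer_queue[[ct]][queue_pos[ct], ]
      queue_pos[ct] <- queue_pos[ct] + 1L
    }
    mz <- if (agent$params$spec$mood == "none") NULL else mood_z[t]
    dv <- decision_value(offer, agent$params, mz)
    p <- choice_probability(dv, ct, agent$params, mz)
    choice <- if (stats::runif(1) < p) "costly" else "uncostly"
    advantage <- if (choice == "costly") dv else -dv
    rt <- max(0.05, agent$rt_params$base -
                agent$rt_params$value_slope * advantage) *
      exp(stats::rnorm(1, 0, agent$rt_params$noise_sd))
    if (sampler == "otg") {
      otg_state[[ct]]$history <- dplyr::bind_rows(
        otg_state[[ct]]$history,
        dplyr::mutate(offer, choice = choice)
      )
      otg_state[[ct]]$model <- update_indifference_model(
        otg_state[[ct]]$history, otg_cfg
      )
    }
    rows[[t]] <- dplyr::bind_cols(
      slots[t, ],
      offer[, c("small_reward", "cost_level", "big_reward", "loss")],
      tibble::tibble(mood_raw = mood_raw[t], mood_z = mood_z[t],
                     dv = dv, p_costly = p, choice = choice, rt = rt)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (sampler == "otg") attr(out, "otg_state") <- otg_state
  out
}

#' Simulate a full multi-session experiment for one agent
#'
#' Stacks `n_sessions` sessions (fresh schedules, independent episode
#' orders) into one trial log with a `session` column. For the grid and
#' random samplers the per-cost-type offer budget is spread across the
#' whole experiment (e.g. an 8 x 8 lattice over two 128-trial sessions
#' gives the 64 offers per cost type of the standard design).
#'
#' @inheritParams simulate_session
#' @param n_sessions Number of sessions (default 2).
#' @param grid_n Lattice size for the grid sampler (in
#'   {9, 16, 25, 36, 64}); when smaller than the per-type trial count
#'   of the experiment, the remaining trials present uniform-random
#'   offers (padding that keeps the session running; analyses truncate
#'   to the first `grid_n` choices per cost type). Defaults to the
#'   smallest lattice covering the experiment.
#' @return Trial-record tibble with a leading `session` column.
#' @export
simulate_experiment <- function(agent, n_sessions = 2,
                                sampler = c("otg", "grid", "random"),
                                otg_cfg = otg_config(),
                                grid = build_grids(), grid_n = NULL) {
  sampler <- match.arg(sampler)
  offer_queue <- NULL
  if (sampler != "otg") {
    total_per_type <- n_sessions * 32L
    types <- cost_types()
    if (sampler == "grid" && is.null(grid_n)) {
      sizes <- c(9, 16, 25, 36, 64)
      grid_n <- min(sizes[sizes >= min(total_per_type, 64)])
    }
    offer_queue <- purrr::map(
      stats::setNames(types, types),
      function(ct) {
        if (sampler == "grid") {
          q <- baseline_sampler("grid", grid_n, grid, ct)
          if (nrow(q) < total_per_type) {
            q <- dplyr::bind_rows(
              q, baseline_sampler("random", total_per_type - nrow(q),
                                  grid, ct)
            )
          }
          q
        } else {
          baseline_sampler("random", total_per_type, grid, ct)
        }
      }
    )
  }
  sessions <- purrr::map(seq_len(n_sessions), function(s) {
    sched <- make_session_schedule()
    if (!is.null(offer_queue)) {
      take <- purrr::map(offer_queue, function(q) {
        idx <- seq((s - 1) * 32 + 1, s * 32)
        q[idx[idx <= nrow(q)], ]
      })
      trials <- simulate_session(agent, sched, sampler, otg_cfg, grid,
                                 offer_queue = take)
    } else {
      trials <- simulate_session(agent, sched, sampler, otg_cfg, grid)
    }
    dplyr::mutate(trials, session = s, .before = 1)
  })
  dplyr::bind_rows(sessions)
}

#' Write a trial log with its agent ground truth
#'
#' The canonical trial-log CSV (one row per trial) plus a JSON sidecar
#' holding the generating parameters, for recovery studies.
#'
#' @param trials Trial-record tibble.
#' @param agent The generating `agent_profile` (optional).
#' @param path CSV path; the sidecar is `<path>.agent.json`.
#' @return `trials`, invisibly.
#' @export
write_trial_log <- function(trials, path, agent = NULL) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  if (!is.null(agent)) {
    truth <- list(
      spec = spec_code(agent$params$spec),
      params = as.list(agent_param_row(agent)),
      mood_params = agent$mood_params,
      rt_params = agent$rt_params
    )
    jsonlite::write_json(truth, paste0(path, ".agent.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(trials)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
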