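#' Generate one 128-trial mood-induction session schedule
#'
#' A session interleaves a general-knowledge quiz (whose feedback drives
#' mood) with one economic choice per trial. It contains two positive and
#' two negative 18-trial episodes in a random order, each flanked before
#' and after by its own 7-trial transition block, for a total of
#' 4 x 18 + 8 x 7 = 128 trials. The feedback bias (proportion of incorrect
#' quiz answers given positive feedback) is 50% / 25% / 0% in positive /
#' transition / negative trials, and question difficulty tracks the
#' condition through the expected correct-answer rate (50.6% / 35.8% /
#' 21.6% by default). Each consecutive group of four trials probes each
#' cost type exactly once, with no cost type on two adjacent trials.
#'
#' @param seed Optional integer; if supplied, seeds the RNG so the
#'   schedule is reproducible. If `NULL`, the current RNG state is used.
#' @param p_correct Named numeric vector of correct-answer probabilities
#'   per condition (`positive`, `transition`, `negative`).
#' @return A tibble of class `session_schedule` with one row per trial:
#'   `index`, `condition`, `feedback_bias`, `p_correct`, `cost_type`.
#' @export
#' @examples
#' sched <- make_session_schedule(seed = 1)
#' dplyr::count(sched, condition)
make_session_schedule <- function(seed = NULL,
                                  p_correct = c(positive = 0.506,
                                                transition = 0.358,
                                                negative = 0.216)) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(episode_conditions() %in% names(p_correct)))

  # episode order: two positive + two negative, randomly permuted
  episodes <- sample(c("positive", "positive", "negative", "negative"))
  condition <- unlist(lapply(episodes, function(ep) {
    c(rep("transition", 7), rep(ep, 18), rep("transition", 7))
  }))

  bias <- c(positive = 0.50, transition = 0.25, negative = 0.0)

  tibble::new_tibble(
    tibble::tibble(
      index = seq_along(condition),
      condition = condition,
      feedback_bias = unname(bias[condition]),
      p_correct = unname(p_correct[condition]),
      cost_type = sample_cost_type_sequence(length(condition))
    ),
    class = "session_schedule"
  )
}

# Cost-type sequence: blocks of four, each a permutation of the four cost
# types, with the boundary constraint (no type twice in a row) enforced by
# rejection-resampling the block permutation -- cheap and unbiased among
# the valid orders.
sample_cost_type_sequence <- function(n_trials) {
  stopifnot(n_trials %% 4 == 0)
  types <- cost_types()
  blocks <- vector("list", n_trials / 4)
  last <- NA_character_
  for (b in seq_along(blocks)) {
    repeat {
      perm <- sample(types)
      if (is.na(last) || perm[1] != last) break
    }
    blocks[[b]] <- perm
    last <- perm[4]
  }
  unlist(blocks)
}

#' Write or read a session schedule as CSV
#'
#' @param schedule A `session_schedule` tibble.
#' @param path File path.
#' @return `write_session_schedule()` returns `schedule` invisibly;
#'   `read_session_schedule()` returns the schedule tibble.
#' @export
write_session_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(schedule)
}

#' @rdname write_session_schedule
#' @export
read_session_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::new_tibble(tibble::as_tibble(df), class = "session_schedule")
}
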