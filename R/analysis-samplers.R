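#' Compare OTG against baseline samplers by simulation
#'
#' The validation study for the adaptive procedure: for each simulated
#' agent (drawn from the population distribution), dummy choices are
#' generated under each sampling method, the target choice model is
#' refitted to them, and three performance metrics are recorded --
#' balanced predictive accuracy, mean posterior variance of the
#' parameter estimates, and (across simulations) the correlation between
#' generating and recovered parameters. The full-scale analysis of this
#' design uses a number of simulations equal to the cube of the model's
#' free-parameter count (13^3 = 2197 for the winning mood-free model,
#' 14^3 = 2744 when the mood weight is added); see
#' [full_scale_n_simulations()]. Scaled-down runs preserve the
#' qualitative ordering.
#'
#' Fit failures are never dropped silently: failed simulations appear as
#' flagged rows with `NA` metrics, and attempted = succeeded + flagged.
#'
#' Balanced accuracy is computed on a common probe set: for each
#' simulated agent, one set of uniformly drawn offers (shared by all
#' samplers and budgets, answered by the agent at neutral mood) is
#' predicted by every fitted model. This compares the fitted models on
#' equal footing -- the adaptive sampler concentrates its *training*
#' trials near indifference, where choices are intrinsically
#' unpredictable, so in-sample accuracy (also reported, as
#' `balanced_accuracy_insample`) reflects trial difficulty more than
#' model quality.
#'
#' @param n_simulations Number of simulated agents (>= 3).
#' @param trial_budgets Per-cost-type trial counts to evaluate (subset
#'   of the full 64; the log is truncated to the first `budget` choices
#'   per cost type before fitting).
#' @param samplers Subset of `c("otg", "grid", "random")`.
#' @param spec Model spec of the generating agent and of the fit.
#' @param seed Optional integer seed.
#' @param n_restarts Optimizer restarts per fit (2 is plenty in
#'   simulation batches).
#' @param n_probe Size of the common probe set used for balanced
#'   accuracy (default 512).
#' @param agent_args List of arguments passed to [sample_agent()].
#' @return An object of class `sampling_comparison`: `per_sim` (one row
#'   per simulation x sampler x budget), `summary` (mean balanced
#'   accuracy and posterior variance per sampler x budget, with
#'   attempted / succeeded / flagged counts) and `correlations`
#'   (recovery correlation per sampler x budget x parameter).
#' @export
run_sampling_comparison <- function(n_simulations,
                                    trial_budgets = 64,
                                    samplers = c("otg", "random"),
                                    spec = winning_model_spec("additive"),
                                    seed = NULL, n_restarts = 2,
                                    n_probe = 512, agent_args = list()) {
  stopifnot(n_simulations >= 3)
  if (!is.null(seed)) set.seed(seed)
  samplers <- match.arg(samplers, c("otg", "grid", "random"),
                        several.ok = TRUE)
  n_sessions <- ceiling(max(trial_budgets) / 32)
  grid <- build_grids()

  per_sim <- purrr::map_dfr(seq_len(n_simulations), function(i) {
    agent <- do.call(sample_agent, c(list(spec = spec), agent_args))
    truth <- agent_param_row(agent)
    probe <- offers(
      rep_len(cost_types(), n_probe),
      small_reward = sample(grid$reward_levels, n_probe, replace = TRUE),
      cost_level = sample(grid$cost_levels, n_probe, replace = TRUE)
    )
    probe$mood_z <- 0
    p_true <- choice_probability(
      decision_value(probe, agent$params, probe$mood_z),
      probe$cost_type, agent$params, probe$mood_z
    )
    probe$choice <- ifelse(stats::runif(n_probe) < p_true,
                           "costly", "uncostly")
    purrr::map_dfr(samplers, function(sm) {
      log <- if (sm == "grid") NULL else {
        simulate_experiment(agent, n_sessions = n_sessions, sampler = sm)
      }
      purrr::map_dfr(trial_budgets, function(b) {
        # the grid sampler needs a budget-sized lattice, so it gets a
        # fresh experiment per budget; otg/random logs are truncated
        log_b <- if (sm == "grid") {
          simulate_experiment(agent, n_sessions = ceiling(b / 32),
                              sampler = "grid", grid_n = b)
        } else log
        sub <- dplyr::slice_head(
          dplyr::group_by(log_b, .data$cost_type), n = b
        )
        sub <- dplyr::ungroup(sub)
        fit <- tryCatch(
          fit_choice_model(sub, spec, n_restarts = n_restarts),
          error = function(e) NULL
        )
        base <- tibble::tibble(sim = i, sampler = sm, n_trials = b)
        if (is.null(fit)) {
          return(dplyr::mutate(base, flagged = TRUE,
                               balanced_accuracy = NA_real_,
                               balanced_accuracy_insample = NA_real_,
                               mean_posterior_variance = NA_real_))
        }
        p_probe <- choice_probability(
          decision_value(probe, fit$params, probe$mood_z),
          probe$cost_type, fit$params, probe$mood_z
        )
        ba <- tryCatch(balanced_accuracy(p_probe, probe$choice),
                       error = function(e) NA_real_)
        ba_in <- tryCatch(balanced_accuracy(fit$predicted_p, sub$choice),
                          error = function(e) NA_real_)
        fitted_row <- stats::setNames(
          as.list(fit$estimates$estimate),
          paste0("fit_", fit$estimates$term)
        )
        dplyr::bind_cols(
          dplyr::mutate(base, flagged = FALSE, balanced_accuracy = ba,
                        balanced_accuracy_insample = ba_in,
                        mean_posterior_variance =
                          mean(fit$estimates$posterior_variance)),
          tibble::as_tibble(fitted_row),
          dplyr::rename_with(truth, ~ paste0("sim_", .x))
        )
      })
    })
  })

  summary <- dplyr::summarise(
    dplyr::group_by(per_sim, .data$sampler, .data$n_trials),
    attempted = dplyr::n(),
    succeeded = sum(!.data$flagged),
    flagged = sum(.data$flagged),
    balanced_accuracy = mean(.data$balanced_accuracy, na.rm = TRUE),
    balanced_accuracy_insample =
      mean(.data$balanced_accuracy_insample, na.rm = TRUE),
    mean_posterior_variance = mean(.data$mean_posterior_variance,
                                   na.rm = TRUE),
    .groups = "drop"
  )

  params <- sub("^sim_", "",
                grep("^sim_", names(per_sim), value = TRUE))
  correlations <- per_sim |>
    dplyr::filter(!.data$flagged) |>
    dplyr::group_by(.data$sampler, .data$n_trials) |>
    dplyr::group_modify(function(d, key) {
      rec <- recovery_metrics(
        stats::setNames(d[paste0("sim_", params)], params),
        stats::setNames(d[paste0("fit_", params)], params)
      )
      rec
    }) |>
    dplyr::ungroup()

  structure(
    list(per_sim = per_sim, summary = summary,
         correlations = correlations, spec = spec),
    class = "sampling_comparison"
  )
}

#' @export
print.sampling_comparison <- function(x, ...) {
  cat("<sampling_comparison> model", spec_code(x$spec), "\n")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' Full-scale simulation budget for a model
#'
#' The convention that a sampling-method validation uses a number of
#' simulations equal to the cube of the free-parameter count: 2197 for
#' the 13-parameter winning model, 2744 once the mood weight makes it
#' 14.
#'
#' @param spec A [model_spec()].
#' @return Integer, `n_free_params(spec)^3`.
#' @export
#' @examples
#' full_scale_n_simulations(winning_model_spec())
#' full_scale_n_simulations(winning_model_spec("additive"))
full_scale_n_simulations <- function(spec) {
  as.integer(n_free_params(spec))^3
}

#' Fit a model set to several subjects and select among models
#'
#' Fits every candidate spec to every subject's trial log, assembles the
#' subjects-by-models log-evidence matrix, and runs random-effects
#' Bayesian model selection on it.
#'
#' @param trial_logs List of trial-record tibbles, one per subject.
#' @param model_set List of [model_spec()]s, or a tibble with a `spec`
#'   list-column (e.g. rows of [enumerate_model_space()]).
#' @param n_restarts Optimizer restarts per fit.
#' @return An object of class `model_comparison`: `evidence` (tibble,
#'   one row per subject x model), `evidence_matrix`, and `bms` (a
#'   [bms()] result; `NULL` when the set has a single model, whose
#'   exceedance probability is then trivially 1).
#' @export
run_model_comparison <- function(trial_logs, model_set, n_restarts = 2) {
  stopifnot(length(trial_logs) >= 1)
  if (is.data.frame(model_set)) model_set <- model_set$spec
  codes <- purrr::map_chr(model_set, spec_code)
  evidence <- purrr::imap_dfr(trial_logs, function(log, s) {
    purrr::map2_dfr(model_set, codes, function(spec, code) {
      fit <- fit_choice_model(log, spec, n_restarts = n_restarts)
      tibble::tibble(subject = s, model = code,
                     log_evidence = fit$log_evidence)
    })
  })
  mat <- tidyr::pivot_wider(evidence, names_from = "model",
                            values_from = "log_evidence")
  m <- as.matrix(mat[, codes, drop = FALSE])
  rownames(m) <- mat$subject
  res <- if (length(model_set) >= 2) {
    bms(m)
  } else {
    # single-model set: selection is trivial
    structure(
      list(summary = tibble::tibble(model = codes,
                                    expected_frequency = 1,
                                    exceedance_probability = 1),
           alpha = stats::setNames(1 + length(trial_logs), codes),
           responsibilities = matrix(1, length(trial_logs), 1,
                                     dimnames = list(NULL, codes))),
      class = "bms_result"
    )
  }
  structure(
    list(evidence = evidence, evidence_matrix = m, bms = res),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>", nrow(x$evidence_matrix), "subjects x",
      ncol(x$evidence_matrix), "models\n")
  if (!is.null(x$bms)) print(x$bms)
  invisible(x)
}

#' Write or read a subjects-by-models evidence matrix as CSV
#'
#' @param x A `model_comparison` or a bare evidence matrix.
#' @param path File path.
#' @return The evidence matrix (invisibly for the writer).
#' @export
write_evidence_csv <- function(x, path) {
  m <- if (inherits(x, "model_comparison")) x$evidence_matrix else x
  utils::write.csv(data.frame(subject = rownames(m), m,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(m)
}

#' @rdname write_evidence_csv
#' @export
read_evidence_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject
  m
}
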