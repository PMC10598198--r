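#' Random-effects Bayesian model selection
#'
#' Group-level model comparison allowing different subjects to use
#' different models: the population frequencies of the candidate models
#' get a Dirichlet prior (uniform, `alpha0 = 1`), and the variational
#' posterior is obtained by iterating the standard fixed-point update on
#' the subjects-by-models log-evidence matrix until the Dirichlet counts
#' change by less than `tol`. Reported are the expected model
#' frequencies and the exceedance probability of each model -- the
#' posterior probability that it is the most frequent in the population,
#' estimated by Monte-Carlo draws from the posterior Dirichlet.
#'
#' @param log_evidence Numeric matrix, subjects in rows, models in
#'   columns (finite; column names become model labels).
#' @param alpha0 Dirichlet prior counts (scalar or per model).
#' @param n_mc Monte-Carlo draws for the exceedance probabilities
#'   (default 1e5).
#' @param tol Convergence tolerance on the Dirichlet counts.
#' @return An object of class `bms_result` with tibble `summary`
#'   (`model`, `expected_frequency`, `exceedance_probability`), the
#'   posterior `alpha`, and the per-subject posterior model
#'   probabilities `responsibilities`.
#' @export
#' @examples
#' lev <- cbind(a = rnorm(10), b = rnorm(10) - 3)
#' bms(lev)$summary
bms <- function(log_evidence, alpha0 = 1, n_mc = 1e5, tol = 1e-6) {
  lev <- as.matrix(log_evidence)
  if (!all(is.finite(lev))) stop("log evidence must be finite")
  n <- nrow(lev)
  K <- ncol(lev)
  if (n < 1 || K < 2) stop("need at least one subject and two models")
  labels <- colnames(lev)
  if (is.null(labels)) labels <- paste0("model", seq_len(K))

  alpha0 <- rep_len(alpha0, K)
  alpha <- alpha0 + n / K
  for (iter in seq_len(500)) {
    lw <- sweep(lev, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  # exceedance: P(model k has the largest population frequency)
  draws <- matrix(stats::rgamma(n_mc * K, shape = rep(alpha, each = n_mc)),
                  n_mc, K)
  winner <- max.col(draws, ties.method = "first")
  ep <- tabulate(winner, K) / n_mc

  structure(
    list(
      summary = tibble::tibble(
        model = labels,
        expected_frequency = alpha / sum(alpha),
        exceedance_probability = ep
      ),
      alpha = stats::setNames(alpha, labels),
      responsibilities = u
    ),
    class = "bms_result"
  )
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result> random-effects model selection,",
      nrow(x$responsibilities), "subjects x",
      nrow(x$summary), "models\n")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' @rdname bms
#' @param x A `bms_result`.
#' @param ... Unused.
#' @export
tidy.bms_result <- function(x, ...) {
  x$summary
}

#' Balanced predictive accuracy of choice predictions
#'
#' The mean of the per-class accuracies over costly and uncostly
#' choices, with predictions thresholded at 0.5 -- insensitive to class
#' imbalance, unlike raw accuracy.
#'
#' @param predicted_p Predicted costly-choice probabilities.
#' @param choices Observed choices (`"costly"`/`"uncostly"`).
#' @return Balanced accuracy in [0, 1].
#' @export
balanced_accuracy <- function(predicted_p, choices) {
  stopifnot(length(predicted_p) == length(choices))
  y <- choices == "costly"
  if (!any(y) || all(y)) {
    stop("balanced accuracy undefined: only one choice class present")
  }
  pred <- predicted_p > 0.5
  mean(c(mean(pred[y]), mean(!pred[!y])))
}

#' Parameter-recovery correlations
#'
#' Pearson correlation, per parameter, between the generating values and
#' the fitted values across simulations. A parameter whose fitted (or
#' simulated) values are constant has an undefined correlation; it is
#' reported as 0 with `degenerate = TRUE`.
#'
#' @param simulated,fitted Data frames with one row per simulation and
#'   one column per parameter (matching names).
#' @return Tibble with `parameter`, `correlation`, `degenerate`.
#' @export
recovery_metrics <- function(simulated, fitted) {
  common <- intersect(names(simulated), names(fitted))
  if (length(common) == 0) stop("no common parameter columns")
  if (nrow(simulated) < 3) stop("need at least 3 simulations for correlations")
  stopifnot(nrow(simulated) == nrow(fitted))
  purrr::map_dfr(common, function(nm) {
    s <- simulated[[nm]]
    f <- fitted[[nm]]
    degenerate <- stats::sd(s) < 1e-12 || stats::sd(f) < 1e-12
    tibble::tibble(
      parameter = nm,
      correlation = if (degenerate) 0 else stats::cor(s, f),
      degenerate = degenerate
    )
  })
}
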