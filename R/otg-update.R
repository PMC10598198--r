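#' Configuration of the online indifference fitter
#'
#' @param temperature Fixed softmax inverse temperature of the online
#'   likelihood, per unit of normalized reward (default 30, i.e. 1 per
#'   euro on the 30 EUR scale -- the choice consistency of the
#'   prior-typical decision maker, whose fitted temperatures are
#'   centred at 1 per euro).
#' @param window Sliding-window size: only this many most recent choices
#'   enter each refit (default 20), so the curve can track preference
#'   drift (e.g. with mood).
#' @param min_obs Updating starts only once this many choices have been
#'   observed (default 3); before that the prior model is returned.
#' @param prior_sd Prior standard deviation of the log-scale slopes
#'   (default 1: slopes within roughly \[0.1, 10\] are plausible).
#' @param b0_log_mean,b0_log_sd Prior mean and sd of `log(b0)`; the
#'   bonus is constrained positive via an exponential transform with its
#'   prior mass just above zero (default mean -3, i.e. b0 ~ 0.05).
#' @param grad_tol Gradient-norm tolerance of the MAP optimizer; on
#'   failure the fit restarts from the prior mean.
#' @return A list of class `otg_config`.
#' @export
otg_config <- function(temperature = 30, window = 20, min_obs = 3,
                       prior_sd = 1, b0_log_mean = -3, b0_log_sd = 1,
                       grad_tol = 1e-6) {
  structure(
    list(temperature = temperature, window = window, min_obs = min_obs,
         prior_sd = prior_sd, b0_log_mean = b0_log_mean,
         b0_log_sd = b0_log_sd, grad_tol = grad_tol),
    class = "otg_config"
  )
}

otg_prior_mean <- function(config) {
  c(config$b0_log_mean, rep(0, 5))  # log scale: slopes centred at 1
}

otg_prior_sd <- function(config) {
  c(config$b0_log_sd, rep(config$prior_sd, 5))
}

#' The prior indifference model of the online fitter
#'
#' Slopes at their prior mean of 1 (the unit linear curve) and the
#' uncostly bonus at its just-above-zero prior value.
#'
#' @param config An [otg_config()].
#' @return An `indifference_model`.
#' @export
otg_prior_model <- function(config = otg_config()) {
  theta <- otg_prior_mean(config)
  indifference_model(b0 = exp(theta[1]), k = exp(theta[-1]),
                     temperature = config$temperature)
}

# Negative log posterior and its gradient on the unconstrained scale
# theta = (log b0, log k1..log k5). The linear predictor is
# eta = temperature * (r*(C) - r) with r*(C) = 1 - X beta, beta = exp(theta).
otg_neg_log_post <- function(theta, X, r, y, config) {
  beta <- exp(theta)
  eta <- config$temperature * (1 - drop(X %*% beta) - r)
  # log Bernoulli via plogis on the signed predictor (numerically safe)
  ll <- sum(stats::plogis(ifelse(y, eta, -eta), log.p = TRUE))
  pm <- otg_prior_mean(config)
  ps <- otg_prior_sd(config)
  -ll + 0.5 * sum(((theta - pm) / ps)^2)
}

otg_neg_log_post_grad <- function(theta, X, r, y, config) {
  beta <- exp(theta)
  eta <- config$temperature * (1 - drop(X %*% beta) - r)
  p <- stats::plogis(eta)
  grad_beta <- config$temperature * drop(crossprod(X, y - p))
  pm <- otg_prior_mean(config)
  ps <- otg_prior_sd(config)
  grad_beta * beta + (theta - pm) / ps^2
}

#' Refit the indifference model from recent choices
#'
#' The sliding-window Bayesian update at the heart of OTG: after every
#' choice, the 6-parameter curve is refitted from its fixed prior using
#' at most the `window` most recent observations of one cost type (a MAP
#' estimate under the fixed-temperature softmax likelihood, positivity
#' enforced by fitting on the log scale; the posterior covariance is the
#' inverse curvature at the MAP -- a Laplace approximation). With fewer
#' than `min_obs` observations the prior model is returned unchanged.
#'
#' @param history Tibble of past choices for a single cost type, oldest
#'   first, with columns `cost_level`, `small_reward`, `choice`
#'   (`"costly"`/`"uncostly"`), and optionally `cost_type` (validated).
#' @param config An [otg_config()].
#' @param laplace Compute the posterior covariance? Skipping it (the
#'   default inside tight simulation loops) saves a Hessian evaluation;
#'   the MAP point is unaffected.
#' @return An `indifference_model` at the MAP, with `posterior` set when
#'   `laplace = TRUE`.
#' @export
update_indifference_model <- function(history, config = otg_config(),
                                      laplace = FALSE) {
  if (!is.null(history$cost_type) &&
      length(unique(history$cost_type)) > 1) {
    stop("`history` mixes cost types; fit one model per cost type.")
  }
  if (nrow(history) < config$min_obs) return(otg_prior_model(config))
  h <- utils::tail(history, config$window)
  X <- piecewise_design(h$cost_level)
  r <- h$small_reward
  y <- h$choice == "costly"

  fit_from <- function(start) {
    stats::optim(start, otg_neg_log_post, otg_neg_log_post_grad,
                 X = X, r = r, y = y, config = config,
                 method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-10))
  }
  start <- otg_prior_mean(config)
  opt <- fit_from(start)
  g <- otg_neg_log_post_grad(opt$par, X, r, y, config)
  if (opt$convergence != 0 || sqrt(sum(g^2)) > config$grad_tol * 100) {
    opt2 <- fit_from(otg_prior_mean(config) +
                       stats::rnorm(6, sd = 0.1))
    if (opt2$value < opt$value) opt <- opt2
  }
  theta <- opt$par
  posterior <- NULL
  if (laplace) {
    H <- stats::optimHess(theta, otg_neg_log_post, otg_neg_log_post_grad,
                          X = X, r = r, y = y, config = config)
    cov <- tryCatch(solve(H), error = function(e) {
      solve(H + diag(1e-6, 6))
    })
    posterior <- list(mean = theta, cov = cov)
  }
  indifference_model(b0 = exp(theta[1]), k = exp(theta[-1]),
                     temperature = config$temperature,
                     posterior = posterior)
}

#' Least-squares fit of the piecewise curve to an arbitrary shape
#'
#' Convenience used to demonstrate the flexibility of the 6-parameter
#' curve: finds the nonnegative `(b0, k)` minimizing the squared error
#' to target rewards at the given cost levels.
#'
#' @param C Cost levels in (0, 1].
#' @param target Target equivalent rewards at `C`.
#' @return An `indifference_model`.
#' @export
fit_indifference_curve <- function(C, target) {
  X <- piecewise_design(C)
  obj <- function(theta) {
    pred <- 1 - drop(X %*% exp(theta))
    sum((pred - target)^2)
  }
  opt <- stats::optim(c(-6, rep(0, 5)), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  indifference_model(b0 = exp(opt$par[1]), k = exp(opt$par[-1]))
}
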