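# --- parameter-vector mapping ------------------------------------------
# Free parameters are fitted on an unconstrained scale: positive ones
# (k_rew, k, gamma, beta1) as logs with Gaussian prior N(0, 1) -- i.e.
# centred at 1 on the natural scale -- and the real-valued beta0 and
# beta_mood directly with prior N(0, 2). The layout is a pure function
# of the model spec.

theta_layout <- function(spec) {
  nm <- character(0)
  scale <- character(0)
  add <- function(names, sc) {
    nm <<- c(nm, names)
    scale <<- c(scale, rep(sc, length(names)))
  }
  if (spec$reward_weight) add("k_rew", "log")
  add(paste0("k_", cost_types()), "log")
  if (spec$free_power) add(paste0("gamma_", cost_types()), "log")
  if (spec$temperature == "shared") add("beta1", "log")
  if (spec$temperature == "specific") add(paste0("beta1_", cost_types()), "log")
  if (spec$bias == "shared") add("beta0", "id")
  if (spec$bias == "specific") add(paste0("beta0_", cost_types()), "id")
  if (spec$mood != "none") add("beta_mood", "id")
  list(names = nm, scale = scale)
}

theta_to_params <- function(theta, spec) {
  lay <- theta_layout(spec)
  names(theta) <- lay$names
  get4 <- function(prefix, scheme, fixed) {
    if (scheme == "absent") return(fixed)
    if (scheme == "shared") return(rep(theta[[prefix]], 4))
    unname(theta[paste0(prefix, "_", cost_types())])
  }
  discount_params(
    spec = spec,
    k_rew = if (spec$reward_weight) exp(theta[["k_rew"]]) else 1,
    k = exp(unname(theta[paste0("k_", cost_types())])),
    gamma = if (spec$free_power) {
      exp(unname(theta[paste0("gamma_", cost_types())]))
    } else NULL,
    beta1 = if (spec$temperature == "absent") 1 else {
      exp(get4("beta1", spec$temperature, 1))
    },
    beta0 = get4("beta0", spec$bias, 0),
    beta_mood = if (spec$mood != "none") theta[["beta_mood"]] else 0
  )
}

params_to_theta <- function(params) {
  spec <- params$spec
  lay <- theta_layout(spec)
  th <- numeric(length(lay$names))
  names(th) <- lay$names
  for (nm in lay$names) {
    val <- switch(
      sub("_(risk|delay|physical_effort|mental_effort)$", "", nm),
      k_rew = params$k_rew,
      k = params$k[[sub("^k_", "", nm)]],
      gamma = params$gamma[[sub("^gamma_", "", nm)]],
      beta1 = if (nm == "beta1") params$beta1[[1]] else
        params$beta1[[sub("^beta1_", "", nm)]],
      beta0 = if (nm == "beta0") params$beta0[[1]] else
        params$beta0[[sub("^beta0_", "", nm)]],
      beta_mood = params$beta_mood
    )
    th[nm] <- if (lay$scale[match(nm, lay$names)] == "log") log(val) else val
  }
  th
}

theta_prior_sd <- function(spec, sd_log = 1, sd_id = 2) {
  lay <- theta_layout(spec)
  ifelse(lay$scale == "log", sd_log, sd_id)
}

# signed linear predictor of the softmax, safe at extremes
choice_log_lik <- function(trials, params) {
  mood_z <- if (params$spec$mood == "none") NULL else trials$mood_z
  dv <- decision_value(trials, params, mood_z)
  b0 <- params$beta0[trials$cost_type]
  if (params$spec$mood == "additive") {
    b0 <- b0 * (1 + params$beta_mood * mood_z)
  }
  eta <- b0 + params$beta1[trials$cost_type] * dv
  y <- trials$choice == "costly"
  sum(stats::plogis(ifelse(y, eta, -eta), log.p = TRUE))
}

#' Fit a choice model to a trial log (MAP + Laplace evidence)
#'
#' Maximum a posteriori estimation of the spec's free parameters under
#' Gaussian priors on an unconstrained scale: positive parameters (cost
#' weights, reward weight, powers, inverse temperatures) are fitted as
#' logs with prior N(0, 1) -- centred at 1 on the natural scale -- and
#' the biases `beta0` and `beta_mood` directly with prior N(0, 2). The
#' log model evidence is approximated by Laplace's method at the MAP
#' (log joint with the prior's normalizing constants +
#' `p/2 log(2 pi) + 1/2 log|Sigma|`), the same convention for every
#' model so that only evidence differences matter in model comparison.
#' Optimization is multi-start BFGS (prior mean plus seeded jitters);
#' the best iterate is kept and a warning is emitted if none
#' converged. For the additive mood model the posterior has a
#' reflected mode (all biases and the mood weight negated), which is
#' optimized explicitly; when a distinct second mode exists the
#' reported `estimates` are posterior means under the two-mode Laplace
#' mixture, the between-mode spread enters `posterior_variance`, and
#' the evidence sums both modes.
#'
#' @param trials Tibble with one row per choice: `cost_type`,
#'   `small_reward`, `cost_level`, `choice` (`"costly"`/`"uncostly"`),
#'   plus `mood_z` when the spec has a mood term. A `loss` column is
#'   reconstructed from the cost type if absent.
#' @param spec A [model_spec()].
#' @param n_restarts Number of optimizer starts (default 5).
#' @param prior_sd_log,prior_sd_id Prior standard deviations on the log
#'   and identity scales.
#' @return An object of class `choice_fit`: the MAP `params`, tibble
#'   `estimates` (term, estimate on the natural scale, posterior
#'   variance on the fitting scale), `log_evidence`, per-trial
#'   `predicted_p`, and convergence info.
#' @export
fit_choice_model <- function(trials, spec = winning_model_spec(),
                             n_restarts = 5, prior_sd_log = 1,
                             prior_sd_id = 2) {
  if (nrow(trials) == 0) stop("no trials to fit")
  if (!"loss" %in% names(trials)) {
    trials$loss <- ifelse(trials$cost_type == "risk",
                          LOSS_EUR / BIG_REWARD_EUR, 0)
  }
  if (spec$mood != "none" && !"mood_z" %in% names(trials)) {
    stop("mood model requires a `mood_z` column")
  }
  lay <- theta_layout(spec)
  p <- length(lay$names)
  psd <- theta_prior_sd(spec, prior_sd_log, prior_sd_id)

  nlp <- function(theta) {
    prm <- tryCatch(theta_to_params(theta, spec), error = function(e) NULL)
    if (is.null(prm)) return(1e10)
    ll <- choice_log_lik(trials, prm)
    if (!is.finite(ll)) return(1e10)
    -ll + 0.5 * sum((theta / psd)^2)
  }

  starts <- c(list(rep(0, p)),
              purrr::map(seq_len(max(0, n_restarts - 1)),
                         ~ stats::rnorm(p, sd = 0.5)))
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    opt <- stats::optim(s, nlp, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) converged <- TRUE
  }
  # the additive mood model has a reflected mode: negating all biases
  # and the mood weight preserves the beta0 * beta_mood products that
  # dominate when |beta_mood| is large. Explicitly optimize from the
  # reflection of the best solution; when a distinct second mode
  # exists, point estimates are posterior means under the two-mode
  # Laplace mixture (weights from each mode's local evidence) and the
  # between-mode spread enters the posterior variance.
  alt <- NULL
  if (spec$mood == "additive" && spec$bias != "absent") {
    flip <- best$par
    idx <- grepl("^beta0", lay$names) | lay$names == "beta_mood"
    flip[idx] <- -flip[idx]
    opt_f <- stats::optim(flip, nlp, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-10))
    if (opt_f$convergence == 0) converged <- TRUE
    if (opt_f$value < best$value) {
      alt <- best
      best <- opt_f
    } else if (sqrt(sum((opt_f$par - best$par)^2)) > 1e-2) {
      alt <- opt_f
    }
  }
  if (!converged) {
    warning("choice-model optimization did not converge; returning best iterate")
  }
  theta <- best$par
  H <- stats::optimHess(theta, nlp)
  cov <- tryCatch(solve(H), error = function(e) solve(H + diag(1e-6, p)))
  # guard: near-singular curvature can yield tiny negative variances
  pv <- pmax(diag(cov), 0)
  log_det <- determinant(cov, logarithm = TRUE)
  # Laplace: log joint at the MAP (including the Gaussian prior's
  # normalizing constants) + (p/2) log(2 pi) + 1/2 log|Sigma|; the
  # 2-pi terms cancel against the prior normalization, leaving the
  # Occam factor sum(log prior_sd) that penalizes unused parameters
  log_evidence <- -best$value - sum(log(psd)) +
    0.5 * as.numeric(log_det$modulus)

  natural_of <- function(th) ifelse(lay$scale == "log", exp(th), th)
  est_mean <- natural_of(theta)
  if (!is.null(alt)) {
    H_a <- stats::optimHess(alt$par, nlp)
    cov_a <- tryCatch(solve(H_a), error = function(e) {
      solve(H_a + diag(1e-6, p))
    })
    ev_a <- -alt$value - sum(log(psd)) +
      0.5 * as.numeric(determinant(cov_a, logarithm = TRUE)$modulus)
    w_a <- 1 / (1 + exp(log_evidence - ev_a))
    nat_a <- natural_of(alt$par)
    est_mean <- (1 - w_a) * est_mean + w_a * nat_a
    pv <- (1 - w_a) * pv + w_a * pmax(diag(cov_a), 0) +
      w_a * (1 - w_a) * (theta - alt$par)^2
    log_evidence <- log_evidence + log1p(exp(ev_a - log_evidence))
  }

  params <- theta_to_params(theta, spec)
  if (spec$mood == "additive" && any(abs(params$beta0) < 1e-3)) {
    warning("fitted |beta0| < 1e-3: the additive mood term has almost no lever")
  }
  mood_z <- if (spec$mood == "none") NULL else trials$mood_z
  dv <- decision_value(trials, params, mood_z)
  predicted_p <- choice_probability(dv, trials$cost_type, params, mood_z)

  structure(
    list(
      spec = spec,
      params = params,
      theta = stats::setNames(theta, lay$names),
      posterior_cov = cov,
      estimates = tibble::tibble(
        term = lay$names,
        estimate = unname(est_mean),
        posterior_variance = unname(pv)
      ),
      log_evidence = log_evidence,
      log_posterior = -best$value,
      predicted_p = predicted_p,
      n_trials = nrow(trials),
      converged = converged
    ),
    class = "choice_fit"
  )
}

#' @export
print.choice_fit <- function(x, ...) {
  cat("<choice_fit> ", spec_code(x$spec), ": ", x$n_trials,
      " trials, log evidence ", round(x$log_evidence, 2), "\n", sep = "")
  print(x$estimates, n = nrow(x$estimates))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted choice model
#'
#' @param x A `choice_fit`.
#' @param ... Unused.
#' @return One row per free parameter: `term`, `estimate` (natural
#'   scale), `posterior_variance` (fitting scale).
#' @export
tidy.choice_fit <- function(x, ...) {
  x$estimates
}

#' One-row summary of a fitted choice model
#'
#' @param x A `choice_fit`.
#' @param ... Unused.
#' @return Tibble with the model code, parameter count, trial count,
#'   log evidence, balanced accuracy and convergence flag.
#' @export
glance.choice_fit <- function(x, ...) {
  tibble::tibble(
    model = spec_code(x$spec),
    n_params = n_free_params(x$spec),
    n_trials = x$n_trials,
    log_evidence = x$log_evidence,
    mean_posterior_variance = mean(x$estimates$posterior_variance),
    converged = x$converged
  )
}
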