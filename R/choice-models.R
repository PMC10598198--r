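#' Construct a full parameter set for a choice model
#'
#' Parameters are stored fully materialized (one value per cost type for
#' the weights, powers, temperatures and biases) together with the owning
#' [model_spec()], which records which of them are free. Values a spec
#' fixes are forced to their fixed values: `k_Rew = 1` when the reward
#' weight is absent, powers `(1, 1, 2, 2)` when fixed, `beta1 = 1` when
#' the temperature is absent, `beta0 = 0` when the bias is absent, and
#' `beta_mood = 0` when there is no mood term. Shared schemes accept a
#' scalar which is recycled across cost types.
#'
#' All quantities are on the normalized internal scale: rewards as
#' fractions of 30 EUR, the risk loss as 1/3, costs in (0, 1].
#'
#' @param spec A `model_spec`.
#' @param k_rew Reward weight (> 0).
#' @param k Cost weights, length 4 (or scalar), order [cost_types()].
#' @param gamma Cost powers, length 4 (or scalar).
#' @param beta1 Softmax inverse temperature(s) (> 0).
#' @param beta0 Softmax additive bias(es).
#' @param beta_mood Mood weight.
#' @return An object of class `discount_params`.
#' @export
#' @examples
#' discount_params(winning_model_spec(), k = c(1, 0.5, 1, 1), beta1 = 2)
discount_params <- function(spec = winning_model_spec(), k_rew = 1, k = 1,
                            gamma = NULL, beta1 = 1, beta0 = 0,
                            beta_mood = 0) {
  stopifnot(inherits(spec, "model_spec"))
  full <- function(x, default) {
    if (is.null(x)) x <- default
    x <- rep_len(x, 4)
    names(x) <- cost_types()
    x
  }
  if (!spec$reward_weight) k_rew <- 1
  if (!spec$free_power) gamma <- c(1, 1, 2, 2)
  if (spec$temperature == "absent") beta1 <- 1
  if (spec$bias == "absent") beta0 <- 0
  if (spec$mood == "none") beta_mood <- 0
  p <- list(
    spec = spec,
    k_rew = k_rew,
    k = full(k, 1),
    gamma = full(gamma, c(1, 1, 2, 2)),
    beta1 = full(beta1, 1),
    beta0 = full(beta0, 0),
    beta_mood = beta_mood
  )
  with(p, stopifnot(k_rew > 0, all(k > 0), all(gamma > 0), all(beta1 > 0)))
  structure(p, class = "discount_params")
}

#' @export
print.discount_params <- function(x, ...) {
  cat("<discount_params> ", spec_code(x$spec), "\n", sep = "")
  cat("  k_rew =", signif(x$k_rew, 4), "  beta_mood =",
      signif(x$beta_mood, 4), "\n")
  m <- rbind(k = x$k, gamma = x$gamma, beta1 = x$beta1, beta0 = x$beta0)
  print(signif(m, 4))
  invisible(x)
}

# Effective reward weight under multiplicative mood modulation.
effective_k_rew <- function(params, mood_z) {
  if (params$spec$mood == "multiplicative" && !is.null(mood_z)) {
    params$k_rew * (1 + params$beta_mood * mood_z)
  } else {
    rep_len(params$k_rew, if (is.null(mood_z)) 1L else length(mood_z))
  }
}

#' Subjective value of the costly option
#'
#' Applies the discount function of each offer's cost type. Offer
#' attributes are stored normalized (big reward = 1, costs in (0, 1]),
#' but subjective values are expressed in euros -- the reward unit of
#' the task, and the scale on which the softmax temperatures and their
#' centred-at-1 priors live:
#' * risk: `k_Rew * 30 * P - k_R * 10 * (1 - P)^gamma_R` with win
#'   probability `P = 1 - cost_level` (the loss at stake is 10 EUR);
#' * delay: `k_Rew * 30 * exp(-k_D * D^gamma_D)`;
#' * physical / mental effort: `k_Rew * 30 - k * 30 * C^gamma` (a
#'   unit cost weight wipes out the full reward at maximum effort).
#'
#' Delay-discounted values are always positive; risk and effort values
#' can go negative (a costly prospect can be worse than nothing).
#'
#' @param offer_tbl A tibble of [offers()].
#' @param params A `discount_params`.
#' @param mood_z Optional z-scored mood ratings (used only by the
#'   multiplicative mood variant, which scales `k_Rew`).
#' @return Numeric vector of subjective values.
#' @export
value_costly <- function(offer_tbl, params, mood_z = NULL) {
  ct <- offer_tbl$cost_type
  C <- offer_tbl$cost_level
  if (any(C < 0)) stop("negative cost level")
  k_rew <- effective_k_rew(params, mood_z)
  k <- params$k[ct]
  g <- params$gamma[ct]
  v <- numeric(length(ct))
  risk <- ct == "risk"
  if (any(risk)) {
    P <- 1 - C[risk]
    if (any(P < 0 | P > 1)) stop("win probability outside [0, 1]")
    kr <- if (length(k_rew) > 1) k_rew[risk] else k_rew
    v[risk] <- kr * P - k[risk] * offer_tbl$loss[risk] * (1 - P)^g[risk]
  }
  delay <- ct == "delay"
  if (any(delay)) {
    kr <- if (length(k_rew) > 1) k_rew[delay] else k_rew
    v[delay] <- kr * exp(-k[delay] * C[delay]^g[delay])
  }
  eff <- ct %in% c("physical_effort", "mental_effort")
  if (any(eff)) {
    kr <- if (length(k_rew) > 1) k_rew[eff] else k_rew
    v[eff] <- kr - k[eff] * C[eff]^g[eff]
  }
  v * BIG_REWARD_EUR
}

#' Decision value of an offer
#'
#' `DV = V(costly) - V(uncostly)` where the uncostly value is the sure,
#' immediate and effortless small reward weighted by `k_Rew`, in euros.
#'
#' @inheritParams value_costly
#' @return Numeric vector of decision values (euros).
#' @export
decision_value <- function(offer_tbl, params, mood_z = NULL) {
  k_rew <- effective_k_rew(params, mood_z)
  value_costly(offer_tbl, params, mood_z) -
    k_rew * offer_tbl$small_reward * BIG_REWARD_EUR
}

#' Probability of choosing the costly option
#'
#' The softmax (sigmoid) choice rule. Without a mood term,
#' `P(costly) = sigmoid(beta0 + beta1 * DV)`. The additive mood variant
#' scales the bias, `sigmoid(beta0 * (1 + beta_mood * mood_z) +
#' beta1 * DV)`; at `mood_z = 0` it reduces exactly to the mood-free
#' rule, and when `beta0 = 0` mood has no lever (the fitter warns about
#' near-zero fitted biases). The multiplicative variant leaves the bias
#' untouched -- mood must instead be supplied to [decision_value()],
#' where it scales the reward weight.
#'
#' @param dv Numeric decision values.
#' @param cost_type Character vector of cost-type labels (selects the
#'   per-type `beta0`/`beta1`).
#' @param params A `discount_params`.
#' @param mood_z Z-scored mood ratings; required when the spec's mood
#'   variant is `"additive"`.
#' @return Numeric probabilities in (0, 1).
#' @export
#' @examples
#' p <- discount_params(winning_model_spec())
#' choice_probability(0, "risk", p)  # 0.5 at indifference, no bias
choice_probability <- function(dv, cost_type, params, mood_z = NULL) {
  if (!all(is.finite(dv))) stop("non-finite decision value")
  b0 <- params$beta0[cost_type]
  b1 <- params$beta1[cost_type]
  if (params$spec$mood == "additive") {
    if (is.null(mood_z)) stop("additive mood model requires `mood_z`")
    if (!all(is.finite(mood_z))) stop("non-finite mood_z")
    b0 <- b0 * (1 + params$beta_mood * mood_z)
  }
  stats::plogis(b0 + b1 * dv)
}

#' Simulate choices for a set of offers
#'
#' Bernoulli draws under [choice_probability()], using the current RNG
#' state (seed with `set.seed()` for reproducibility).
#'
#' @inheritParams value_costly
#' @param mood_z Z-scored mood ratings (additive and multiplicative
#'   variants); ignored when the spec has no mood term.
#' @return The offer tibble with added columns `dv`, `p_costly`, and
#'   `choice` (`"costly"` / `"uncostly"`).
#' @export
simulate_choice <- function(offer_tbl, params, mood_z = NULL) {
  dv <- decision_value(offer_tbl, params, mood_z)
  p <- choice_probability(dv, offer_tbl$cost_type, params, mood_z)
  dplyr::mutate(
    offer_tbl,
    dv = dv,
    p_costly = p,
    choice = ifelse(stats::runif(length(p)) < p, "costly", "uncostly")
  )
}
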