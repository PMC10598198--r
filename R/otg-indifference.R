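#' Piecewise-linear indifference model
#'
#' The OTG procedure avoids committing to any parametric discount
#' function: the equivalent small reward `r*(C)` at cost level `C` is an
#' edge-constrained piecewise-linear curve over 5 equal cost bins
#' (`(0, 0.2], (0.2, 0.4], ...`), defined by 6 parameters -- an uncostly
#' bonus `b0` (the intercept offset at zero cost) and 5 bin slopes
#' `k1..k5`. In bin `j`,
#' `r*(C) = 1 - b0 - sum(k[1:(j-1)]) * 0.2 - k[j] * (C - 0.2 * (j - 1))`,
#' so the curve is continuous at every bin edge by construction. The
#' model also carries the fixed softmax inverse temperature used to turn
#' value differences into choice probabilities during online fitting, and
#' (after updating) a Laplace posterior over the log-scale parameters.
#'
#' @param b0 Uncostly bonus, `>= 0`.
#' @param k Five positive bin slopes.
#' @param temperature Fixed softmax inverse temperature per unit of
#'   normalized reward (not a fitted parameter; default 30 = 1 per
#'   euro, see [otg_config()]).
#' @param posterior Optional list with `mean` and `cov` on the
#'   unconstrained (log) scale, as produced by
#'   [update_indifference_model()].
#' @return An object of class `indifference_model`.
#' @export
#' @examples
#' m <- indifference_model(b0 = 0, k = rep(1, 5))
#' indifference_reward(c(0.1, 0.5, 1), m)
indifference_model <- function(b0 = 0, k = rep(1, 5), temperature = 30,
                               posterior = NULL) {
  stopifnot(length(k) == 5, all(k > 0), b0 >= 0, temperature > 0)
  structure(
    list(b0 = b0, k = as.numeric(k), temperature = temperature,
         posterior = posterior),
    class = "indifference_model"
  )
}

#' @export
print.indifference_model <- function(x, ...) {
  cat("<indifference_model> b0 =", signif(x$b0, 4), " k =",
      paste(signif(x$k, 3), collapse = " "),
      " (temperature", x$temperature, ")\n")
  invisible(x)
}

# Design matrix of the piecewise-linear drop: row i gives the
# coefficients of (b0, k1..k5) such that r*(C_i) = 1 - X[i, ] %*% theta.
piecewise_design <- function(C) {
  stopifnot(all(C > 0), all(C <= 1))
  j <- pmin(ceiling(C / 0.2 - 1e-12), 5L)
  X <- matrix(0, length(C), 6)
  X[, 1] <- 1
  for (i in seq_along(C)) {
    if (j[i] > 1) X[i, 1 + seq_len(j[i] - 1)] <- 0.2
    X[i, 1 + j[i]] <- C[i] - 0.2 * (j[i] - 1)
  }
  X
}

#' Equivalent small reward at a given cost level
#'
#' Evaluates the piecewise-linear indifference curve. The result can be
#' negative for steep curves; it is clipped only for display and AUC
#' support, never inside the likelihood.
#'
#' @param C Cost levels in (0, 1].
#' @param model An `indifference_model`.
#' @return Numeric vector `r*(C)`.
#' @export
indifference_reward <- function(C, model) {
  if (any(C <= 0 | C > 1)) stop("cost level must lie inside (0, 1]")
  drop(1 - piecewise_design(C) %*% c(model$b0, model$k))
}

#' Indifference score of a choice probability
#'
#' Distance of a modelled costly-choice probability from 50%, reflected
#' and normalized to span [0, 1]: `(0.5 - |p - 0.5|) / 0.5`. 1 at exact
#' indifference, 0 at certainty either way.
#'
#' @param p_costly Probabilities in [0, 1].
#' @return Scores in [0, 1].
#' @export
#' @examples
#' indifference_score(c(0, 0.5, 0.75, 1))
indifference_score <- function(p_costly) {
  if (any(p_costly < 0 | p_costly > 1)) stop("probability outside [0, 1]")
  (0.5 - abs(p_costly - 0.5)) / 0.5
}

#' Map expected indifference over the reward-by-cost grid
#'
#' For every (small reward, cost level) cell, the modelled costly-choice
#' probability is `sigmoid(temperature * (r*(C) - r))` (the `b0` bonus
#' enters both option values through `r*`, so only the curve matters),
#' scored with [indifference_score()]. Column sums (over rewards, per
#' cost level), normalized to 1, give the sampling density over cost
#' levels: cost levels with more near-indifferent reward combinations are
#' more likely to be probed next.
#'
#' @param model An `indifference_model`.
#' @param grid An `otg_grid`.
#' @return An object of class `indifference_map`: list with the `grid`,
#'   the 50 x 50 `scores` matrix (rewards in rows, costs in columns),
#'   the `cost_density` vector (sums to 1), and the `model`.
#' @export
build_indifference_map <- function(model, grid = build_grids()) {
  r_star <- indifference_reward(grid$cost_levels, model)
  # outer: rows index rewards, columns index cost levels
  dv <- outer(grid$reward_levels, r_star, function(r, rs) rs - r)
  p <- stats::plogis(model$temperature * dv)
  scores <- indifference_score(p)
  sums <- colSums(scores)
  density <- if (sum(sums) > 0) sums / sum(sums) else
    rep(1 / length(sums), length(sums))
  structure(
    list(grid = grid, scores = scores, cost_density = density,
         model = model),
    class = "indifference_map"
  )
}

#' Draw the next offer from an indifference map
#'
#' Samples a cost level from the map's cost density, then pairs it with
#' the grid reward closest to the current indifference estimate `r*(C)`
#' (clipped into the grid range; ties snap to the lower reward). Uses the
#' current RNG state.
#'
#' @param map An `indifference_map`.
#' @param cost_type Cost-type label for the returned offer.
#' @return A one-row [offers()] tibble.
#' @export
sample_next_offer <- function(map, cost_type) {
  grid <- map$grid
  i <- sample.int(length(grid$cost_levels), 1, prob = map$cost_density)
  C <- grid$cost_levels[i]
  r_star <- indifference_reward(C, map$model)
  r_star <- min(max(r_star, min(grid$reward_levels)), max(grid$reward_levels))
  r <- snap_to_grid(r_star, grid$reward_levels)
  offers(cost_type, small_reward = r, cost_level = C)
}

#' Area under the indifference curve
#'
#' A continuous index of the global willingness to accept costs: the
#' trapezoidal integral of the positive part of `r*(C)` over the full
#' cost range (nodes at zero cost, where `r* = 1 - b0`, and the 50
#' grid levels) -- only cost levels with a positive equivalent reward
#' contribute. The flat curve `r* == 1` gives 1, the unit linear curve
#' `r* = 1 - C` gives exactly 0.5, and steepening any bin slope can
#' only lower the AUC.
#'
#' @param model An `indifference_model`.
#' @param grid An `otg_grid`.
#' @return AUC in [0, 1].
#' @export
#' @examples
#' compute_auc(indifference_model(b0 = 0, k = rep(1, 5)))
compute_auc <- function(model, grid = build_grids()) {
  C <- c(0, grid$cost_levels)
  r <- pmax(c(1 - model$b0, indifference_reward(grid$cost_levels, model)),
            0)
  sum((r[-1] + r[-length(r)]) / 2 * diff(C)) / (max(C) - min(C))
}
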