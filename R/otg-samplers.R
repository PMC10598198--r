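#' Grid and random baseline samplers
#'
#' The non-adaptive comparison points for OTG. `"grid"` sampling lays a
#' square lattice of sqrt(n) x sqrt(n) offers equally spaced over the
#' reward-by-cost extents (corners at the extents), for n in
#' {9, 16, 25, 36, 64} -- 64 matching the per-cost-type trial budget of
#' a two-session experiment. `"random"` sampling draws n offers
#' uniformly over the 50 x 50 grid cells. Offers are returned in
#' randomized presentation order (current RNG state).
#'
#' @param kind `"grid"` or `"random"`.
#' @param n Number of offers; for `"grid"` must be a perfect square in
#'   {9, 16, 25, 36, 64}.
#' @param grid An `otg_grid`.
#' @param cost_type Cost-type label stamped on the offers.
#' @param shuffle Randomize presentation order? Default TRUE.
#' @return An [offers()] tibble with `n` rows.
#' @export
#' @examples
#' baseline_sampler("grid", 9, cost_type = "delay", shuffle = FALSE)
baseline_sampler <- function(kind = c("grid", "random"), n,
                             grid = build_grids(), cost_type = "risk",
                             shuffle = TRUE) {
  kind <- match.arg(kind)
  if (kind == "grid") {
    m <- sqrt(n)
    if (!(n %in% c(9, 16, 25, 36, 64))) {
      stop("grid sampling requires n in {9, 16, 25, 36, 64}")
    }
    cl <- seq(min(grid$cost_levels), max(grid$cost_levels), length.out = m)
    rl <- seq(min(grid$reward_levels), max(grid$reward_levels),
              length.out = m)
    pts <- tidyr::expand_grid(cost_level = cl, small_reward = rl)
  } else {
    pts <- tibble::tibble(
      cost_level = sample(grid$cost_levels, n, replace = TRUE),
      small_reward = sample(grid$reward_levels, n, replace = TRUE)
    )
  }
  if (shuffle) pts <- pts[sample.int(nrow(pts)), ]
  offers(cost_type, small_reward = pts$small_reward,
         cost_level = pts$cost_level)
}

#' Serialize and restore OTG state
#'
#' The full state of a running OTG session -- per cost type, the current
#' model (with posterior, when computed) and the choice history feeding
#' the sliding window -- round-trips through JSON so a session can be
#' resumed deterministically.
#'
#' @param state A named list (one element per cost type) of lists with
#'   `model` (an `indifference_model`) and `history` (a tibble).
#' @param path File path for the JSON.
#' @return `write_otg_state()` returns `state` invisibly;
#'   `read_otg_state()` the restored state.
#' @export
write_otg_state <- function(state, path) {
  ser <- purrr::map(state, function(s) {
    list(
      model = list(
        b0 = s$model$b0, k = s$model$k,
        temperature = s$model$temperature,
        posterior_mean = s$model$posterior$mean,
        posterior_cov = s$model$posterior$cov
      ),
      history = as.data.frame(s$history)
    )
  })
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(state)
}

#' @rdname write_otg_state
#' @export
read_otg_state <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  purrr::map(raw, function(s) {
    posterior <- NULL
    if (!is.null(s$model$posterior_mean)) {
      posterior <- list(mean = as.numeric(s$model$posterior_mean),
                        cov = as.matrix(s$model$posterior_cov))
    }
    list(
      model = indifference_model(
        b0 = s$model$b0, k = as.numeric(s$model$k),
        temperature = s$model$temperature, posterior = posterior
      ),
      history = tibble::as_tibble(s$history)
    )
  })
}
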