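#' Construct offers (one binary choice per row)
#'
#' An offer opposes a small uncostly reward (`small_reward`, a fraction of
#' the 30 EUR maximum, strictly below 1) to the fixed large reward
#' (`big_reward = 1`, i.e. 30 EUR) obtainable at `cost_level` (fraction of
#' the cost-type maximum, in (0, 1]). For risk offers the lottery loss is
#' 10 EUR, i.e. 1/3 in reward units; for the other cost types the loss is
#' zero.
#'
#' @param cost_type Character vector of [cost_types()] labels.
#' @param small_reward Numeric in (0, 1), fraction of 30 EUR.
#' @param cost_level Numeric in (0, 1], fraction of the cost maximum.
#' @param costly_side `"left"` or `"right"`, screen side of the costly
#'   option (counterbalancing bookkeeping only; no effect on values).
#' @return A tibble with columns `cost_type`, `small_reward`,
#'   `cost_level`, `big_reward`, `loss`, `costly_side`.
#' @export
#' @examples
#' offers(c("risk", "delay"), small_reward = c(0.4, 0.5), cost_level = c(0.42, 1))
offers <- function(cost_type, small_reward, cost_level,
                   costly_side = "left") {
  stopifnot(all(cost_type %in% cost_types()))
  if (any(small_reward <= 0 | small_reward >= 1)) {
    stop("`small_reward` must lie strictly inside (0, 1).")
  }
  if (any(cost_level <= 0 | cost_level > 1)) {
    stop("`cost_level` must lie inside (0, 1].")
  }
  tibble::tibble(
    cost_type = cost_type,
    small_reward = small_reward,
    cost_level = cost_level,
    big_reward = 1,
    loss = ifelse(cost_type == "risk", LOSS_EUR / BIG_REWARD_EUR, 0),
    costly_side = costly_side
  )
}

#' Convert normalized offers to physical units
#'
#' Maps normalized `(small_reward, cost_level)` pairs to the quantities a
#' participant actually sees: euros (rounded to cents), and the cost in
#' its physical unit -- probability (%) of losing 10 EUR for risk, days
#' out of 365 for delay, steps of stairs out of 12 flights of 14 steps
#' for physical effort (the task displays flights plus remaining
#' steps), lines of text out of 300 (12 pages of 25 lines) for mental
#' effort. Rounding to these display units keeps the conversion
#' invertible within the resolution of the 50-level cost grid.
#'
#' @param offer_tbl A tibble as returned by [offers()].
#' @param grid An `otg_grid` carrying the physical maxima.
#' @return The input tibble with added columns `small_reward_eur`,
#'   `cost_physical`, `cost_unit`, and a human-readable `description`.
#' @export
#' @examples
#' offer_to_physical(offers("risk", 0.5, 0.42))$description
offer_to_physical <- function(offer_tbl, grid = build_grids()) {
  if (any(offer_tbl$cost_level <= 0 | offer_tbl$cost_level > 1)) {
    stop("`cost_level` must lie inside (0, 1].")
  }
  unit_max <- c(risk = 100, delay = grid$max_delay_days,
                physical_effort = grid$max_steps,
                mental_effort = grid$max_lines)
  unit_lab <- c(risk = "% risk of losing 10€", delay = "days",
                physical_effort = "steps", mental_effort = "lines")
  phys <- round(offer_tbl$cost_level * unit_max[offer_tbl$cost_type])
  label <- character(nrow(offer_tbl))
  for (i in seq_len(nrow(offer_tbl))) {
    label[i] <- switch(
      offer_tbl$cost_type[i],
      risk = paste0(phys[i], "% risk of losing 10€"),
      delay = paste0(phys[i], " days"),
      physical_effort = paste0(phys[i] %/% STEPS_PER_FLIGHT, " flights ",
                               phys[i] %% STEPS_PER_FLIGHT, " steps"),
      mental_effort = paste0(phys[i] %/% LINES_PER_PAGE, " pages ",
                             phys[i] %% LINES_PER_PAGE, " lines")
    )
  }
  dplyr::mutate(
    offer_tbl,
    small_reward_eur = round(.data$small_reward * grid$big_reward_eur, 2),
    cost_physical = unname(phys),
    cost_unit = unname(unit_lab[.data$cost_type]),
    description = paste0(
      format(.data$small_reward_eur, nsmall = 2), "€ now vs 30€ at ",
      label
    )
  )
}

#' Recover normalized cost levels from physical units
#'
#' Inverse of [offer_to_physical()]; exact up to the rounding used for
#' display, so round-trips land within grid resolution.
#'
#' @param cost_physical Numeric vector of physical cost quantities.
#' @param cost_type Character vector of cost-type labels.
#' @param grid An `otg_grid`.
#' @return Numeric vector of normalized cost levels in (0, 1].
#' @export
physical_to_cost_level <- function(cost_physical, cost_type,
                                   grid = build_grids()) {
  unit_max <- c(risk = 100, delay = grid$max_delay_days,
                physical_effort = grid$max_steps,
                mental_effort = grid$max_lines)
  unname(cost_physical / unit_max[cost_type])
}
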