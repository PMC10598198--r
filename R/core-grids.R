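#' Cost types probed by the choice task
#'
#' The task trades a fixed large reward (30 EUR) against one of four costs:
#' a risk of losing 10 EUR, a delay until payment (up to one year), a
#' physical effort (flights of stairs to climb, up to 12), or a mental
#' effort (lines of cryptic text to copy). These labels are the stable
#' serialization used in every trial log and result table.
#'
#' @return Character vector of the four cost-type labels, in canonical order.
#' @export
#' @examples
#' cost_types()
cost_types <- function() {
  c("risk", "delay", "physical_effort", "mental_effort")
}

#' Episode conditions of the mood-induction schedule
#'
#' @return Character vector `c("positive", "negative", "transition")`.
#' @export
episode_conditions <- function() {
  c("positive", "negative", "transition")
}

# Canonical scale constants: big reward 30 EUR (= 1 in normalized units),
# potential loss 10 EUR (= 1/3), and the physical maxima each cost maps onto.
BIG_REWARD_EUR <- 30
LOSS_EUR <- 10
MAX_DELAY_DAYS <- 365
MAX_FLIGHTS <- 12
STEPS_PER_FLIGHT <- 14  # display resolution: flights shown with steps
LINES_PER_PAGE <- 25

#' Build the canonical reward-by-cost sampling grid
#'
#' Offers live on a 50 x 50 grid: 50 cost levels equally spaced from 2% to
#' 100% of the cost-type maximum, and 50 small-reward levels equally spaced
#' so that the euro endpoints are 0.10 EUR and 29.90 EUR on the 30 EUR
#' scale (fractions 0.0033 to 0.9967).
#'
#' @param n Number of levels per axis. Default 50.
#' @param max_pages Number of pages defining the mental-effort maximum
#'   (each page has 25 lines). Default 12, by symmetry with the 12 flights
#'   of stairs; the task's displayed copying loads (up to 11 pages and a
#'   line) fit under this maximum.
#' @return An object of class `otg_grid`: a list with numeric vectors
#'   `cost_levels` and `reward_levels` (both strictly increasing, length
#'   `n`) and the physical-unit maxima used by [offer_to_physical()].
#' @export
#' @examples
#' g <- build_grids()
#' range(g$cost_levels)
#' round(g$reward_levels[c(1, 50)] * 30, 2)
build_grids <- function(n = 50, max_pages = 12) {
  stopifnot(n >= 2, max_pages >= 1)
  grid <- list(
    cost_levels = seq(0.02, 1.00, length.out = n),
    reward_levels = seq(0.0033, 0.9967, length.out = n),
    big_reward_eur = BIG_REWARD_EUR,
    loss_eur = LOSS_EUR,
    max_delay_days = MAX_DELAY_DAYS,
    max_flights = MAX_FLIGHTS,
    max_steps = MAX_FLIGHTS * STEPS_PER_FLIGHT,
    max_lines = max_pages * LINES_PER_PAGE
  )
  structure(grid, class = "otg_grid")
}

#' @export
print.otg_grid <- function(x, ...) {
  cat("<otg_grid> ", length(x$cost_levels), " cost levels [",
      format(min(x$cost_levels)), ", ", format(max(x$cost_levels)),
      "] x ", length(x$reward_levels), " reward levels [",
      format(round(min(x$reward_levels) * x$big_reward_eur, 2)), " EUR, ",
      format(round(max(x$reward_levels) * x$big_reward_eur, 2)),
      " EUR]\n", sep = "")
  invisible(x)
}

# Snap a value to the nearest element of a grid vector; ties go to the
# lower level so snapped rewards never overstate the offer.
snap_to_grid <- function(x, levels) {
  vapply(x, function(v) {
    d <- abs(levels - v)
    i <- which(d <= min(d) + 1e-12)[1]
    levels[i]
  }, numeric(1))
}
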