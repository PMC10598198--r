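#' Define one member of the discount/softmax model family
#'
#' A model spec fixes which parts of the choice model carry free
#' parameters. The discount functions always have one weight per cost
#' type (`k_R`, `k_D`, `k_PE`, `k_ME`). On top of that:
#' * `reward_weight`: a shared weight `k_Rew` on the monetary reward
#'   (fixed at 1 when absent);
#' * `free_power`: cost-specific power parameters (curvature), toggled
#'   jointly; when fixed they are 1 for risk and delay and 2 for both
#'   efforts (the standard expected-value / exponential / parabolic
#'   forms);
#' * `temperature`: the softmax inverse temperature `beta1`, either
#'   `"absent"` (fixed at 1), `"shared"` (one parameter) or
#'   `"specific"` (one per cost type);
#' * `bias`: the additive softmax bias `beta0`, `"absent"` (0),
#'   `"shared"` or `"specific"`;
#' * `mood`: how rated mood (z-scored) enters the model: `"none"`,
#'   `"additive"` (mood scales the bias, `beta0 * (1 + beta_mood * mood)`)
#'   or `"multiplicative"` (mood scales the reward weight,
#'   `k_Rew * (1 + beta_mood * mood)`).
#'
#' The model selected by group-level comparison in this family has a free
#' reward weight, fixed powers, and cost-specific temperature and bias
#' (13 parameters); adding the additive mood bias makes 14.
#'
#' @param reward_weight Logical, free `k_Rew`?
#' @param free_power Logical, free cost powers?
#' @param temperature,bias One of `"absent"`, `"shared"`, `"specific"`.
#' @param mood One of `"none"`, `"additive"`, `"multiplicative"`.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' winning_model_spec()
#' n_free_params(winning_model_spec())
model_spec <- function(reward_weight = TRUE, free_power = FALSE,
                       temperature = c("specific", "shared", "absent"),
                       bias = c("specific", "shared", "absent"),
                       mood = c("none", "additive", "multiplicative")) {
  spec <- structure(
    list(
      reward_weight = isTRUE(reward_weight),
      free_power = isTRUE(free_power),
      temperature = match.arg(temperature),
      bias = match.arg(bias),
      mood = match.arg(mood)
    ),
    class = "model_spec"
  )
  spec
}

#' @rdname model_spec
#' @export
winning_model_spec <- function(mood = "none") {
  model_spec(reward_weight = TRUE, free_power = FALSE,
             temperature = "specific", bias = "specific", mood = mood)
}

scheme_count <- c(absent = 0L, shared = 1L, specific = 4L)

#' Number of free parameters of a model spec
#'
#' Cost weights contribute 4; `k_Rew` adds 1; free powers add 4; the
#' temperature and bias schemes add 0 / 1 / 4 each; a mood variant adds 1.
#'
#' @param spec A `model_spec`.
#' @return Integer count.
#' @export
n_free_params <- function(spec) {
  4L + as.integer(spec$reward_weight) + 4L * as.integer(spec$free_power) +
    scheme_count[[spec$temperature]] + scheme_count[[spec$bias]] +
    as.integer(spec$mood != "none")
}

#' Short string code for a model spec
#'
#' Used as the model label in evidence tables and BMS results, e.g.
#' `"kRew+pow0+b1x4+b0x4+moodA"`: reward weight free, powers fixed,
#' cost-specific temperature and bias, additive mood. Scheme suffixes are
#' `x0` (absent), `x1` (shared), `x4` (specific); mood suffixes `N`, `A`,
#' `M`.
#'
#' @param spec A `model_spec`.
#' @return Single string.
#' @export
spec_code <- function(spec) {
  sch <- c(absent = "x0", shared = "x1", specific = "x4")
  paste0(
    if (spec$reward_weight) "kRew" else "kRew0",
    "+", if (spec$free_power) "powF" else "pow0",
    "+b1", sch[[spec$temperature]],
    "+b0", sch[[spec$bias]],
    "+mood", c(none = "N", additive = "A", multiplicative = "M")[[spec$mood]]
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", spec_code(x), " (", n_free_params(x),
      " free parameters)\n", sep = "")
  invisible(x)
}

#' Enumerate the mood-free model space
#'
#' The Cartesian product of reward-weight (on/off), power (free/fixed),
#' temperature scheme and bias scheme (absent/shared/specific each) gives
#' 2 x 2 x 3 x 3 = 36 candidate models, all with `mood = "none"`; the
#' mood variants are compared separately once the mood-free winner is
#' known.
#'
#' @return A tibble with one row per model: the factor columns, the
#'   free-parameter count `n_params`, the string `code`, and a `spec`
#'   list-column of `model_spec` objects, in deterministic order.
#' @export
#' @examples
#' nrow(enumerate_model_space())
enumerate_model_space <- function() {
  grid <- tidyr::expand_grid(
    reward_weight = c(FALSE, TRUE),
    free_power = c(FALSE, TRUE),
    temperature = c("absent", "shared", "specific"),
    bias = c("absent", "shared", "specific")
  )
  specs <- purrr::pmap(grid, function(reward_weight, free_power,
                                      temperature, bias) {
    model_spec(reward_weight, free_power, temperature, bias, mood = "none")
  })
  dplyr::mutate(
    grid,
    n_params = purrr::map_int(specs, n_free_params),
    code = purrr::map_chr(specs, spec_code),
    spec = specs
  )
}
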