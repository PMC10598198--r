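#' Construct a synthetic agent profile
#'
#' An agent bundles everything needed to simulate a participant: the
#' choice-model parameters (with their [model_spec()]), the parameters
#' of the mood generator (a leaky integrator of quiz feedback), and the
#' response-time generator. Defaults for the mood integrator are
#' calibrated so that within-episode mood slopes are of realistic
#' magnitude and negative induction is stronger than positive induction
#' (`gain_neg > gain_pos`), the asymmetry reliably seen with this
#' paradigm.
#'
#' @param params A `discount_params` (carries its spec).
#' @param mood_params List: `decay` (leak, in \[0, 1)), `gain_pos` /
#'   `gain_neg` (mood increments per positive / negative feedback, on
#'   the \[-1, 1\] raw mood scale), `noise_sd`.
#' @param rt_params List: `base` (seconds), `value_slope` (seconds per
#'   euro of decision-value advantage of the chosen option), `noise_sd`
#'   (log scale).
#' @return An object of class `agent_profile`.
#' @export
agent_profile <- function(params,
                          mood_params = list(decay = 0.85, gain_pos = 0.05,
                                             gain_neg = 0.09,
                                             noise_sd = 0.03),
                          rt_params = list(base = 2.0, value_slope = 0.015,
                                           noise_sd = 0.25)) {
  stopifnot(inherits(params, "discount_params"),
            mood_params$decay >= 0, mood_params$decay < 1,
            mood_params$gain_pos >= 0, mood_params$gain_neg >= 0,
            mood_params$noise_sd >= 0, rt_params$base > 0,
            rt_params$noise_sd >= 0)
  structure(
    list(params = params, mood_params = mood_params,
         rt_params = rt_params),
    class = "agent_profile"
  )
}

#' @export
print.agent_profile <- function(x, ...) {
  cat("<agent_profile> choice model", spec_code(x$params$spec), "\n")
  invisible(x)
}

#' Draw a random agent from the population distribution
#'
#' Positive choice parameters (cost weights, reward weight, inverse
#' temperatures, free powers) are drawn log-normal with median 1 and a
#' configurable log-sd; the biases `beta0` are Gaussian (optionally
#' folded positive, for cohorts where mood must have a consistent
#' lever), and `beta_mood` Gaussian with mean 0.6. Uses the current RNG
#' state; the same seed always yields the same agent.
#'
#' @param spec The agent's [model_spec()] (default: winning model with
#'   additive mood).
#' @param log_sd Log-scale sd of the positive parameters (default 0.5).
#' @param beta0_mean,beta0_sd Gaussian parameters of the bias draw.
#' @param beta0_positive Fold the bias positive (half-normal)? Needed
#'   when the additive mood bias must act in a known direction.
#' @param beta_mood_mean,beta_mood_sd Gaussian parameters of the mood
#'   weight.
#' @param ... Passed to [agent_profile()] (mood / RT parameters).
#' @return An `agent_profile`.
#' @export
#' @examples
#' set.seed(1)
#' sample_agent()
sample_agent <- function(spec = winning_model_spec(mood = "additive"),
                         log_sd = 0.5, beta0_mean = 0, beta0_sd = 1,
                         beta0_positive = FALSE, beta_mood_mean = 0.6,
                         beta_mood_sd = 0.3, ...) {
  rpos <- function(n) exp(stats::rnorm(n, 0, log_sd))
  b0 <- stats::rnorm(4, beta0_mean, beta0_sd)
  if (beta0_positive) b0 <- abs(b0)
  params <- discount_params(
    spec = spec,
    k_rew = rpos(1),
    k = rpos(4),
    gamma = if (spec$free_power) rpos(4) else NULL,
    beta1 = rpos(4),
    beta0 = b0,
    beta_mood = stats::rnorm(1, beta_mood_mean, beta_mood_sd)
  )
  agent_profile(params, ...)
}

#' Agent parameters as a one-row tibble
#'
#' The free parameters of the agent's choice model, on the natural
#' scale, named as in [tidy.choice_fit()] -- convenient for
#' recovery-correlation bookkeeping.
#'
#' @param agent An `agent_profile`.
#' @return One-row tibble.
#' @export
agent_param_row <- function(agent) {
  th <- params_to_theta(agent$params)
  lay <- theta_layout(agent$params$spec)
  natural <- ifelse(lay$scale == "log", exp(th), th)
  tibble::as_tibble(as.list(stats::setNames(natural, lay$names)))
}

#' Simulate quiz feedback for scheduled trials
#'
#' Each trial: a correct answer with probability `p_correct` (set by the
#' condition's question difficulty); correct answers always receive
#' positive feedback, incorrect ones receive positive feedback with
#' probability `feedback_bias` (50% / 25% / 0% in positive / transition
#' / negative trials). The expected positive-feedback rate is therefore
#' `p_correct + (1 - p_correct) * bias`.
#'
#' @param slots Tibble with columns `p_correct` and `feedback_bias`
#'   (e.g. a [make_session_schedule()] result).
#' @return `slots` with added logical `correct` and character `feedback`
#'   (`"positive"`/`"negative"`).
#' @export
#' @examples
#' set.seed(1)
#' fb <- simulate_quiz_feedback(make_session_schedule(seed = 1))
#' mean(fb$feedback == "positive")
simulate_quiz_feedback <- function(slots) {
  n <- nrow(slots)
  correct <- stats::runif(n) < slots$p_correct
  lucky <- stats::runif(n) < slots$feedback_bias
  dplyr::mutate(
    slots,
    correct = correct,
    feedback = ifelse(correct | lucky, "positive", "negative")
  )
}

#' Simulate a mood trace from a feedback sequence
#'
#' A leaky integrator on the raw \[-1, 1\] mood scale:
#' `m_t = decay * m_{t-1} + gain_pos * [positive] - gain_neg *
#' [negative] + noise`, starting at 0. This is generator plumbing: mood
#' is measured, not modelled, in the experiments this package emulates;
#' the integrator merely reproduces the qualitative shape (rise during
#' positive episodes, steeper fall during negative ones, relaxation
#' toward baseline in transitions).
#'
#' @param feedbacks Character vector (`"positive"`/`"negative"`).
#' @param mood_params As in [agent_profile()].
#' @return Numeric vector of raw mood values, one per feedback.
#' @export
simulate_mood_trace <- function(feedbacks,
                                mood_params = list(decay = 0.85,
                                                   gain_pos = 0.05,
                                                   gain_neg = 0.09,
                                                   noise_sd = 0.03)) {
  n <- length(feedbacks)
  eps <- stats::rnorm(n, 0, mood_params$noise_sd)
  gain <- ifelse(feedbacks == "positive", mood_params$gain_pos,
                 -mood_params$gain_neg)
  m <- numeric(n)
  prev <- 0
  for (t in seq_len(n)) {
    prev <- mood_params$decay * prev + gain[t] + eps[t]
    m[t] <- prev
  }
  m
}
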