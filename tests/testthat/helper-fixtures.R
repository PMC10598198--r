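# Shared fixtures: everything is generated in code at test time.

# Choices from a known piecewise-linear agent responding at the OTG
# fixed temperature, with offers scattered around its indifference line
# (the informative regime an adaptive session produces).
simulate_indifference_choices <- function(truth, n,
                                          grid = build_grids(),
                                          spread = 0.2,
                                          cost_type = "risk") {
  C <- sample(grid$cost_levels, n, replace = TRUE)
  r_star <- indifference_reward(C, truth)
  r <- pmin(pmax(r_star + stats::runif(n, -spread, spread),
                 min(grid$reward_levels)), max(grid$reward_levels))
  h <- offers(rep(cost_type, n), small_reward = r, cost_level = C)
  p <- stats::plogis(truth$temperature * (r_star - r))
  h$choice <- ifelse(stats::runif(n) < p, "costly", "uncostly")
  h
}

# A deterministic mid-scale agent for fitting tests (temperatures in
# 1/EUR, the task's value unit).
fixed_agent <- function(mood = "additive") {
  agent_profile(discount_params(
    spec = winning_model_spec(mood),
    k_rew = 1, k = c(1, 1.2, 0.8, 1), beta1 = c(1, 0.7, 1, 0.7),
    beta0 = c(1, 0.8, 0.6, 0.7), beta_mood = 0.6
  ))
}
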