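test_that("indifference curve matches hand-computed values and is
           continuous at bin edges", {
  m <- indifference_model(b0 = 0, k = rep(1, 5))
  expect_equal(indifference_reward(0.5, m), 0.5)
  expect_equal(indifference_reward(1, m), 0)
  m2 <- indifference_model(b0 = 0.1, k = c(2, 1, 1, 1, 1))
  expect_equal(indifference_reward(0.1, m2), 1 - 0.1 - 0.2)
  # continuity at all interior bin edges for random parameter draws
  set.seed(2)
  for (i in 1:20) {
    m3 <- indifference_model(b0 = runif(1, 0, 0.3),
                             k = exp(rnorm(5, 0, 0.7)))
    edges <- seq(0.2, 0.8, by = 0.2)
    below <- indifference_reward(edges, m3)
    above <- indifference_reward(edges + 1e-9, m3)
    expect_equal(below, above, tolerance = 1e-6)
  }
  expect_error(indifference_reward(0, m))
  expect_error(indifference_reward(1.01, m))
})

test_that("indifference score is the normalized distance from 50%", {
  expect_equal(indifference_score(0.5), 1)
  expect_equal(indifference_score(0), 0)
  expect_equal(indifference_score(1), 0)
  expect_equal(indifference_score(0.75), 0.5)
  # symmetry about 0.5 over a dense sweep
  p <- seq(0, 1, by = 0.01)
  expect_equal(indifference_score(p), indifference_score(1 - p))
  expect_true(all(indifference_score(p) >= 0 & indifference_score(p) <= 1))
  expect_error(indifference_score(1.2))
})

test_that("indifference map concentrates score on the curve and
           normalizes the cost density", {
  m <- indifference_model(b0 = 0, k = rep(1, 5))
  map <- build_indifference_map(m)
  g <- map$grid
  expect_equal(dim(map$scores), c(50, 50))
  expect_true(all(map$scores >= 0 & map$scores <= 1))
  expect_equal(sum(map$cost_density), 1, tolerance = 1e-12)
  expect_true(all(map$cost_density >= 0))
  # at each cost column the best-scoring reward is the grid point
  # nearest r*(C)
  r_star <- indifference_reward(g$cost_levels, m)
  for (j in c(1, 10, 25, 40, 49)) {
    best <- g$reward_levels[which.max(map$scores[, j])]
    nearest <- g$reward_levels[which.min(abs(g$reward_levels - r_star[j]))]
    expect_equal(best, nearest)
  }
  # vanishing temperature flattens the map into a uniform density
  flat <- build_indifference_map(
    indifference_model(0, rep(1, 5), temperature = 1e-9)
  )
  expect_equal(flat$cost_density, rep(1 / 50, 50), tolerance = 1e-6)
})

test_that("offer sampling follows the cost density and stays on-grid", {
  m <- indifference_model(b0 = 0, k = rep(1, 5))
  map <- build_indifference_map(m)
  g <- map$grid
  # degenerate density: point mass
  map2 <- map
  map2$cost_density <- c(rep(0, 24), 1, rep(0, 25))
  set.seed(4)
  for (i in 1:5) {
    o <- sample_next_offer(map2, "delay")
    expect_equal(o$cost_level, g$cost_levels[25])
  }
  # rewards land within one grid step of the indifference line
  set.seed(5)
  draws <- purrr::map_dfr(1:200, ~ sample_next_offer(map, "risk"))
  expect_true(all(draws$small_reward %in% g$reward_levels))
  expect_true(all(draws$cost_level %in% g$cost_levels))
  step <- diff(g$reward_levels)[1]
  gap <- abs(draws$small_reward - (1 - draws$cost_level))
  expect_true(all(gap <= step / 2 + 1e-9))
  # empirical cost frequencies match the density (chi-square at n=4000)
  set.seed(6)
  idx <- replicate(4000, {
    o <- sample_next_offer(map, "risk")
    which(g$cost_levels == o$cost_level)
  })
  obs <- tabulate(idx, 50)
  keep <- map$cost_density > 1e-6
  chi <- suppressWarnings(
    stats::chisq.test(obs[keep], p = map$cost_density[keep] /
                        sum(map$cost_density[keep]))
  )
  expect_gt(chi$p.value, 1e-4)
})

test_that("online update respects the warm-up and sliding window", {
  cfg <- otg_config()
  set.seed(7)
  truth <- indifference_model(1e-6, rep(1, 5))
  h <- simulate_indifference_choices(truth, 22)
  # fewer than 3 observations: prior verbatim
  prior <- otg_prior_model(cfg)
  got <- update_indifference_model(h[1:2, ], cfg)
  expect_equal(got$b0, prior$b0)
  expect_equal(got$k, prior$k)
  # observation 1 lies outside the 20-trial window: perturbing it is a
  # no-op
  h_perturbed <- h
  h_perturbed$choice[1] <- ifelse(h$choice[1] == "costly",
                                  "uncostly", "costly")
  h_perturbed$small_reward[1] <- 0.9
  m1 <- update_indifference_model(h, cfg)
  m2 <- update_indifference_model(h_perturbed, cfg)
  expect_equal(m1$b0, m2$b0)
  expect_equal(m1$k, m2$k)
  # but perturbing an in-window observation changes the fit
  h_in <- h
  h_in$choice[22] <- ifelse(h$choice[22] == "costly", "uncostly", "costly")
  m3 <- update_indifference_model(h_in, cfg)
  expect_false(isTRUE(all.equal(m1$k, m3$k)))
  expect_error(update_indifference_model(
    dplyr::mutate(h, cost_type = rep(c("risk", "delay"), 11)), cfg
  ))
})

test_that("online update recovers a known linear agent at curve level", {
  # 200 informative choices, full-window refit: the recovered curve
  # r*(C) tracks the generating 1 - C closely; individual slopes are
  # noisier because continuity propagates edge errors at 1/binwidth
  cfg <- otg_config(window = 200)
  set.seed(8)
  truth <- indifference_model(1e-6, rep(1, 5))
  g <- build_grids()
  for (i in 1:5) {
    h <- simulate_indifference_choices(truth, 200)
    m <- update_indifference_model(h, cfg, laplace = TRUE)
    err <- max(abs(indifference_reward(g$cost_levels, m) -
                     (1 - g$cost_levels)))
    expect_lt(err, 0.15)
    expect_lt(m$b0, 0.1)
    # Laplace posterior is a valid covariance
    expect_equal(dim(m$posterior$cov), c(6, 6))
    expect_true(all(eigen(m$posterior$cov)$values > 0))
  }
})

test_that("piecewise curve approximates exponential and parabolic
           discounting within 0.05", {
  g <- build_grids()
  C <- g$cost_levels
  f_exp <- fit_indifference_curve(C, exp(-2 * C))
  expect_lt(max(abs(indifference_reward(C, f_exp) - exp(-2 * C))), 0.05)
  f_par <- fit_indifference_curve(C, 1 - C^2)
  expect_lt(max(abs(indifference_reward(C, f_par) - (1 - C^2))), 0.05)
})

test_that("AUC matches closed forms and responds to slope changes", {
  expect_equal(compute_auc(indifference_model(0, rep(1, 5))), 0.5)
  expect_equal(compute_auc(indifference_model(0, rep(1e-9, 5))), 1,
               tolerance = 1e-6)
  # steeper discounting always lowers the AUC
  base <- compute_auc(indifference_model(0.05, rep(1, 5)))
  for (j in 1:5) {
    k <- rep(1, 5)
    k[j] <- 1.5
    expect_lt(compute_auc(indifference_model(0.05, k)), base)
  }
})

test_that("baseline samplers produce the advertised designs", {
  g <- build_grids()
  o9 <- baseline_sampler("grid", 9, cost_type = "delay", shuffle = FALSE)
  expect_equal(nrow(o9), 9)
  expect_equal(sort(unique(o9$cost_level)),
               seq(0.02, 1, length.out = 3))
  expect_equal(sort(unique(o9$small_reward)),
               seq(0.0033, 0.9967, length.out = 3))
  expect_error(baseline_sampler("grid", 10))
  o64 <- baseline_sampler("grid", 64)
  expect_equal(nrow(o64), 64)
  # random sampling is uniform over cost levels
  set.seed(9)
  oR <- baseline_sampler("random", 4000)
  chi <- suppressWarnings(
    stats::chisq.test(tabulate(match(oR$cost_level, g$cost_levels), 50))
  )
  expect_gt(chi$p.value, 1e-4)
})

test_that("closed-loop OTG concentrates offers near the agent's
           indifference curve", {
  set.seed(10)
  agent <- fixed_agent("none")
  trials <- simulate_session(agent, make_session_schedule(seed = 10),
                             sampler = "otg")
  # distance between presented reward and the agent's true equivalent
  # reward, early vs late
  p <- agent$params
  r_true <- function(d) {
    v <- value_costly(d, p)  # euros
    b0 <- p$beta0[d$cost_type]
    b1 <- p$beta1[d$cost_type]
    # agent indifferent when b0 + b1 (v - 30 k_rew r) = 0
    (v + b0 / b1) / (30 * p$k_rew)
  }
  gap <- abs(trials$small_reward - r_true(trials))
  early <- median(gap[trials$index <= 32])
  late <- median(gap[trials$index > 96])
  expect_lt(late, early)
})

test_that("OTG state round-trips through JSON and resumes identically", {
  set.seed(12)
  agent <- fixed_agent("none")
  sched <- make_session_schedule(seed = 12)
  trials <- simulate_session(agent, sched[1:64, ], sampler = "otg")
  state <- attr(trials, "otg_state")
  path <- withr::local_tempfile(fileext = ".json")
  write_otg_state(state, path)
  state2 <- read_otg_state(path)
  for (ct in cost_types()) {
    expect_equal(state2[[ct]]$model$k, state[[ct]]$model$k)
    expect_equal(state2[[ct]]$model$b0, state[[ct]]$model$b0)
    expect_equal(as.data.frame(state2[[ct]]$history),
                 as.data.frame(state[[ct]]$history))
  }
  # resuming from the restored state reproduces the continuation
  set.seed(99)
  cont1 <- simulate_session(agent, sched[65:128, ], sampler = "otg",
                            otg_state = state)
  set.seed(99)
  cont2 <- simulate_session(agent, sched[65:128, ], sampler = "otg",
                            otg_state = state2)
  expect_equal(cont1$choice, cont2$choice)
  expect_equal(cont1$small_reward, cont2$small_reward)
})
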