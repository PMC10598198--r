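test_that("agent sampling is seed-deterministic with the stated
           population distribution", {
  set.seed(18)
  a1 <- sample_agent()
  set.seed(18)
  a2 <- sample_agent()
  expect_equal(agent_param_row(a1), agent_param_row(a2))
  # degenerate draw: zero log-sd pins positive parameters at 1
  set.seed(18)
  a3 <- sample_agent(log_sd = 0)
  expect_equal(unname(a3$params$k), rep(1, 4))
  expect_equal(a3$params$k_rew, 1)
  # log-normal median 1: median k_delay over many draws near 1
  set.seed(19)
  ks <- replicate(2000, sample_agent()$params$k[["delay"]])
  expect_gt(median(ks), 0.9)
  expect_lt(median(ks), 1.1)
  # default asymmetry: negative feedback moves mood more than positive
  expect_gt(a1$mood_params$gain_neg, a1$mood_params$gain_pos)
})

test_that("quiz feedback rates follow p_correct + (1 - p_correct) * bias
           in every condition", {
  set.seed(20)
  n <- 4e4
  for (cond in list(c(p = 0.506, b = 0.5), c(p = 0.358, b = 0.25),
                    c(p = 0.216, b = 0))) {
    slots <- tibble::tibble(p_correct = cond[["p"]],
                            feedback_bias = cond[["b"]],
                            index = 1:n)
    fb <- simulate_quiz_feedback(slots)
    expected <- cond[["p"]] + (1 - cond[["p"]]) * cond[["b"]]
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(mean(fb$feedback == "positive") - expected), 3.5 * se)
    # correct answers are always rewarded
    expect_true(all(fb$feedback[fb$correct] == "positive"))
    if (cond[["b"]] == 0) {
      expect_true(all(fb$feedback[!fb$correct] == "negative"))
    }
  }
})

test_that("mood trace integrates feedback with leak and asymmetry", {
  mp <- list(decay = 0, gain_pos = 0.1, gain_neg = 0.2, noise_sd = 0)
  m <- simulate_mood_trace(c("positive", "negative", "positive"), mp)
  expect_equal(m, c(0.1, -0.2, 0.1))
  # geometric approach to the all-positive fixed point
  mp2 <- list(decay = 0.8, gain_pos = 0.1, gain_neg = 0.2, noise_sd = 0)
  m2 <- simulate_mood_trace(rep("positive", 200), mp2)
  expect_equal(m2[200], 0.1 / (1 - 0.8), tolerance = 1e-8)
  expect_true(all(diff(m2) > -1e-12))
  # on a standard schedule: mood rises within positive episodes and
  # falls (more steeply) within negative ones
  set.seed(21)
  slopes <- purrr::map_dfr(1:40, function(i) {
    s <- make_session_schedule()
    fb <- simulate_quiz_feedback(s)
    fb$mood <- simulate_mood_trace(fb$feedback)
    ep <- fb[fb$condition != "transition", ]
    new_ep <- c(TRUE, diff(ep$index) != 1)
    ep$ep_id <- cumsum(new_ep)
    purrr::map_dfr(split(ep, ep$ep_id), function(d) {
      tibble::tibble(
        condition = d$condition[1],
        slope = stats::coef(stats::lm(d$mood ~ seq_len(nrow(d))))[2]
      )
    })
  })
  mean_pos <- mean(slopes$slope[slopes$condition == "positive"])
  mean_neg <- mean(slopes$slope[slopes$condition == "negative"])
  expect_gt(mean_pos, 0)
  expect_lt(mean_neg, 0)
  expect_gt(abs(mean_neg), abs(mean_pos))
})

test_that("a simulated session has the full design and coupling to mood
           only through beta_mood", {
  set.seed(22)
  agent <- fixed_agent("additive")
  trials <- simulate_session(agent, make_session_schedule(seed = 22))
  expect_equal(nrow(trials), 128)
  expect_equal(unname(table(trials$cost_type)), rep(32L, 4),
               ignore_attr = TRUE)
  expect_true(all(trials$rt > 0))
  expect_equal(mean(trials$mood_z), 0, tolerance = 1e-10)
  expect_equal(sd(trials$mood_z), 1, tolerance = 1e-10)

  # no mood coupling: choice-rate contrast averages to ~0 over seeded
  # closed-loop sessions (offers near indifference, where a bias would
  # show if present)
  rate_contrast <- function(tr) {
    mean(tr$choice[tr$condition == "positive"] == "costly") -
      mean(tr$choice[tr$condition == "negative"] == "costly")
  }
  set.seed(23)
  agent0 <- agent_profile(discount_params(
    winning_model_spec("additive"),
    k = c(1, 1.2, 0.8, 1), beta1 = c(1, 0.7, 1, 0.7),
    beta0 = c(1, 0.8, 0.6, 0.7), beta_mood = 0
  ))
  d0 <- purrr::map_dbl(1:12, function(i) {
    rate_contrast(simulate_session(agent0, make_session_schedule(),
                                   sampler = "otg"))
  })
  expect_lt(abs(mean(d0)), 3 * sd(d0) / sqrt(length(d0)) + 0.01)

  # positive mood coupling raises the costly-choice rate in positive
  # episodes
  set.seed(24)
  d1 <- purrr::map_dbl(1:12, function(i) {
    rate_contrast(simulate_session(agent, make_session_schedule(),
                                   sampler = "otg"))
  })
  expect_lt(stats::t.test(d1, alternative = "greater")$p.value, 0.05)
  expect_gt(mean(d1), mean(d0))
})

test_that("OTG keeps presented offers independent of the episode
           condition", {
  set.seed(25)
  agent <- fixed_agent("additive")
  logs <- purrr::map_dfr(1:10, function(i) {
    simulate_session(agent, make_session_schedule(), sampler = "otg")
  })
  pos <- logs[logs$condition == "positive", ]
  neg <- logs[logs$condition == "negative", ]
  expect_lt(abs(mean(pos$small_reward) - mean(neg$small_reward)), 0.05)
  expect_lt(abs(mean(pos$cost_level) - mean(neg$cost_level)), 0.05)
})

test_that("trial logs round-trip through CSV with the agent sidecar", {
  set.seed(26)
  agent <- fixed_agent("additive")
  trials <- simulate_session(agent, make_session_schedule(seed = 26),
                             sampler = "random")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(trials, path, agent = agent)
  back <- read_trial_log(path)
  expect_equal(back$choice, trials$choice)
  expect_equal(back$mood_z, trials$mood_z, tolerance = 1e-12)
  truth <- jsonlite::read_json(paste0(path, ".agent.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$spec, "kRew+pow0+b1x4+b0x4+moodA")
  expect_equal(truth$params$beta_mood, agent$params$beta_mood)
})
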