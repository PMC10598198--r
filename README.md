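# moodchoice

Tools for studying how incidental mood shifts cost–benefit tradeoffs in
economic decisions. The package is aimed at behavioural and
computational researchers running (or simulating) tasks in which a
small sure reward is traded against a fixed large reward carrying a
risk, delay, physical-effort or mental-effort cost, while mood is
pushed up and down by biased feedback on an unrelated quiz.

Its core is **online trial generation (OTG)**: a closed-loop adaptive
procedure that keeps every offer near the decision maker's current
indifference point. The equivalent small reward at cost level *C* is an
edge-constrained piecewise-linear curve with an uncostly bonus *b₀* and
five bin slopes *k₁..k₅*,

    r*(C) = 1 − b₀ − 0.2·Σ_{i<j} k_i − k_j·(C − 0.2(j−1)),   C in bin j,

refitted after every choice (MAP under a fixed-temperature softmax,
sliding 20-trial window, log-scale positivity, Laplace posterior). The
next offer samples a cost level in proportion to the summed
indifference score (0.5 − |p − 0.5|)/0.5 over a 50×50 reward-by-cost
grid and pairs it with the grid reward nearest r*(C).

Around that core the package provides:

* the 36-member discount/softmax model family (expected-value risk,
  exponential delay, parabolic effort discounting; shared/specific/absent
  temperature and bias schemes) plus additive and multiplicative mood
  variants, `P(costly) = σ(β₀·(1 + β_Mood·mood) + β₁·DV)`;
* MAP inversion with a Laplace model evidence, broom-style `tidy()` /
  `glance()` methods, and random-effects Bayesian model selection
  (expected frequencies, exceedance probabilities);
* a synthetic-agent simulator reproducing the full design — 128-trial
  sessions, 18-trial mood episodes with 50%/25%/0% feedback bias,
  leaky-integrator mood, closed-loop choices and response times;
* study drivers: sampler comparison (OTG vs grid vs random), cohort
  model comparison, RT preprocessing, and the model-free mood-effect
  battery (choice-rate contrasts, choice~mood logistic regressions,
  RT interactions, AUC time courses).

Everything takes and returns tibbles, so analyses chain with the pipe.

## Worked example

```r
library(moodchoice)
set.seed(7)

# one synthetic participant with a positive mood bias
agent  <- sample_agent(beta0_positive = TRUE)
trials <- simulate_experiment(agent, n_sessions = 2, sampler = "otg")
dplyr::count(trials, condition, choice)
#> # A tibble: 6 x 3
#>   condition  choice       n
#>   <chr>      <chr>    <int>
#> 1 negative   costly      36
#> 2 negative   uncostly    36
#> 3 positive   costly      48
#> 4 positive   uncostly    24
#> 5 transition costly      64
#> 6 transition uncostly    48
```

The costly-choice rate is 67% in positive episodes against 50% in
negative ones: the adaptive sampler keeps offers near indifference,
where the agent's additive mood bias visibly shifts choices toward the
costly option. Refitting the generating (14-parameter) model recovers
the mood weight:

```r
fit <- fit_choice_model(trials, winning_model_spec("additive"))
dplyr::filter(tidy(fit), term == "beta_mood")
#> # A tibble: 1 x 3
#>   term      estimate posterior_variance
#>   <chr>        <dbl>              <dbl>
#> 1 beta_mood    0.633             0.0465
glance(fit)$log_evidence
#> [1] -130.2701
```

The simulated agent's true `beta_mood` was 0.70; the MAP estimate is
0.63 with posterior variance 0.046 on the fitting scale. A cohort of
such logs goes to `analyze_mood_effects()` for the group-level
battery, and to `run_model_comparison()` +` bms()` to ask which model
variant the population uses.

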