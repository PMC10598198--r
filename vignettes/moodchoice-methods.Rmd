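---
title: "Methods: adaptive indifference tracking and mood-modulated choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive indifference tracking and mood-modulated choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodchoice)
```

## The scientific problem

Incidental mood is known to shift economic preferences: people accept
risk, delay and effort more readily when in a good mood. Measuring that
shift within participants requires choices pitched near each person's
*indifference point* — where a small sure reward and a larger costly
reward are equally attractive — because far from indifference a small
bias cannot change the observed choice. `moodchoice` implements the
full toolchain for studying this: a closed-loop adaptive trial
generator (OTG, online trial generation) that keeps offers near
indifference while preferences drift, a family of discount/softmax
choice models with a mood-modulated bias, Bayesian model inversion and
random-effects model selection, and a synthetic-cohort simulator for
validating the whole pipeline.

## The task being emulated

Each trial couples a quiz question (whose feedback drives mood) with
one binary economic choice: a small uncostly reward (0.10–29.90 EUR)
against a fixed 30 EUR reward carrying one of four costs — a risk of
losing 10 EUR, a delay up to one year, up to 12 flights of stairs, or
up to 12 pages (25 lines each) of cryptic text to copy. A session has
128 trials: two positive and two negative 18-trial episodes in random
order, each flanked by its own 7-trial transition block
(4×18 + 8×7 = 128). The feedback bias — the share of *incorrect* quiz
answers that still receive positive feedback — is 50%/25%/0% in
positive/transition/negative trials, and question difficulty tracks the
condition (default correct-answer rates 50.6%/35.8%/21.6%). Each run of
four consecutive trials probes each cost type once, never twice in a
row.

Design choices worth stating:

* **Transition blocks are not shared** between adjacent episodes: only
  4×18 + 8×7 reproduces the 128-trial session length.
* **The mental-effort maximum** is set to 12 pages (300 lines) by
  symmetry with the 12 flights of stairs; it is configurable in
  `build_grids()`.
* The cost-type constraint at block boundaries is enforced by
  rejection-resampling the block permutation — cheap and unbiased among
  valid orders.
* Whether episode order should be counterbalanced across the two
  sessions is unspecified in the designs we emulate; we randomize
  independently per session.

## The indifference model and OTG

OTG avoids committing to a parametric discount function. The
equivalent small reward at cost level $C$ is an edge-constrained
piecewise-linear curve over five equal cost bins,

$$r^*(C) = 1 - b_0 - 0.2\sum_{i<j} k_i - k_j\,(C - 0.2(j-1)),
\qquad C \in \text{bin } j,$$

with six parameters: an uncostly bonus $b_0 \ge 0$ (equivalent to a
softmax bias toward the uncostly side) and five positive bin slopes
$k_1..k_5$. Continuity at bin edges is built into the formula. The
curve can approximate convex and concave discounting alike; the test
suite verifies a maximum absolute error below 0.05 against both
$e^{-2C}$ and $1 - C^2$ on the 50-point cost grid.

After every choice the curve is refitted — from its fixed prior, on at
most the 20 most recent choices of that cost type (so preferences may
drift, e.g. with mood), starting only once 3 choices exist. The
likelihood is a softmax with a *fixed* inverse temperature on the
normalized value scale; the fit is a MAP estimate with positivity
enforced on the log scale, and a Laplace (inverse-curvature) posterior
covariance on demand. One independent model is maintained per cost
type, because each type is probed every fourth trial.

Numerical choices:

* **Fixed OTG temperature**: default 30 per unit of normalized reward,
  i.e. 1 per euro on the 30 EUR scale — the choice consistency of the
  prior-typical decision maker (fitted temperatures are centred at 1
  per euro). It is a tool setting, not a fitted parameter, and is
  configurable in `otg_config()`; a value far below the population's
  actual consistency makes the online curve over-smooth the evidence
  and spread offers away from indifference.
* **Priors**: slopes log-normal centred at 1 (log-sd 1, making slopes
  in roughly [0.1, 10] plausible); $b_0 = e^{z_0}$ with
  $z_0 \sim N(-3, 1)$, i.e. prior mass just above zero.
* **Optimizer**: BFGS with analytic gradients; on non-convergence the
  fit restarts from a jittered prior mean and the better optimum is
  kept.
* **Slope vs curve recovery**: continuity propagates errors in the
  estimated $r^*$ at bin edges into slopes at rate $1/0.2$, so
  individual slopes are intrinsically noisy at realistic trial counts
  while the curve itself is tight; recovery tests therefore assert
  accuracy of $r^*(C)$ (and of $b_0$), not of single slopes.

To pick the next offer, the modelled costly-choice probability
$p = \sigma\!\left(\beta_{\text{OTG}}\,(r^*(C) - r)\right)$ is scored
with the indifference score $(0.5 - |p - 0.5|)/0.5$ over a 50×50
reward-by-cost grid; cost levels are sampled in proportion to their
column score sums, and the reward is the grid point nearest $r^*(C)$
(ties toward the lower reward). A continuous readout of the global
willingness to accept costs is the area under the indifference curve
(AUC): the trapezoidal integral of $r^*$ over consecutive grid costs
where $r^* > 0$, normalized by the included cost span — so the flat
curve $r^* \equiv 1$ scores 1 and the unit linear curve scores exactly
0.5. (Normalizing by the fixed grid span instead would make the linear
curve score 0.49; we normalize by the included span so both anchor
values hold.)

## The choice-model family

Subjective values use the standard forms, in euros (the task's reward
unit, and the scale on which the temperatures and their centred-at-1
priors live): expected value with a loss term for risk,
$V_R = 30\,k_{Rew} P - 10\,k_R (1-P)^{\gamma_R}$ with $P = 1 - C$;
multiplicative exponential decay for delay,
$V_D = 30\,k_{Rew} e^{-k_D D^{\gamma_D}}$; additive parabolic costs
for both efforts, $V = 30\,(k_{Rew} - k\,C^{\gamma})$ — the cost
weights act on normalized cost levels, so a unit weight wipes out the
full reward at maximum cost. Fixed powers are 1 (risk, delay) and 2
(efforts). Delay values stay positive; risk and effort values may go
negative. Choice probability is
$\sigma(\beta_0 + \beta_1 \cdot DV)$ with
$DV = V(\text{costly}) - 30\,k_{Rew}\, r$, $\beta_1$ in 1/EUR.
Keeping values on the euro scale matters: a median inverse
temperature of 1 describes a reasonably consistent decision maker per
euro of value difference, which is the population the centred-at-1
priors and the sampler-validation studies assume.

The model space crosses reward weight (on/off) × powers (free/fixed,
toggled jointly across cost types) × temperature scheme × bias scheme
(absent / shared / specific each), 36 members, mood-free. An *absent*
temperature is interpreted as $\beta_1 \equiv 1$ — a softmax needs a
temperature, and fixing it at 1 is the only parameter-free reading.
The winning member (free $k_{Rew}$, fixed powers, cost-specific
$\beta_1$ and $\beta_0$) has 13 free parameters.

Mood enters in one of two ways, compared by model selection:
*additive*, $\beta_0 (1 + \beta_{Mood} \cdot \text{mood}_z)$, or
*multiplicative*, scaling $k_{Rew}$ by the same factor inside $DV$.
The additive form degenerates when $\beta_0 = 0$ (mood has no lever);
the fitter warns when a fitted $|\beta_0| < 10^{-3}$. The mood
covariate is the per-session z-scored rating, matching analysis-time
practice.

## Inversion and model selection

Models are inverted by MAP estimation on an unconstrained scale
(positive parameters as logs, Gaussian prior $N(0,1)$ — centred at 1
naturally; $\beta_0, \beta_{Mood} \sim N(0, 2)$, chosen wide), with
multi-start BFGS (default 5 starts; simulation batches use 2). The log
model evidence is a Laplace approximation at the MAP,
$\log p(y|\hat\theta)p(\hat\theta) + \tfrac{p}{2}\log 2\pi +
\tfrac12 \log |\Sigma|$ — one consistent convention across models, so
selection depends only on evidence differences. A full variational
inversion would be an alternative; any consistent evidence
approximation supports the same comparisons. Group-level selection is
the standard random-effects scheme: a variational Dirichlet update on
the subjects-by-models evidence matrix, with exceedance probabilities
by $10^5$ Monte-Carlo Dirichlet draws.

## The synthetic cohort

`sample_agent()` draws choice parameters log-normal with median 1
(log-sd 0.5), $\beta_0 \sim N(0,1)$ (optionally folded positive when a
cohort needs mood to act in a known direction), and
$\beta_{Mood} \sim N(0.6, 0.3)$. Mood is generated by a leaky
integrator of feedback,
$m_t = \lambda m_{t-1} + w^+ [f=+] - w^- [f=-] + \varepsilon_t$ on a
[-1, 1] raw scale, with defaults $\lambda = 0.85$, $w^+ = 0.05$,
$w^- = 0.09$, noise sd 0.03 — calibrated so within-episode mood slopes
are small and negative induction is stronger than positive, the
asymmetry this paradigm reliably produces. Mood is *measured*, not
mechanistically modelled, in the experiments we emulate; the
integrator only reproduces the qualitative shape. Ratings are z-scored
per session after simulation (two-pass), the same scale the analyses
use. Response times are
$\max(\text{base} - s \cdot \text{advantage}, 0.05)$ times log-normal
noise, where advantage is the decision value of the *chosen* option —
a convenience for exercising the RT analyses, not a mechanism claim.

What the generator deliberately does not emulate: quiz content and
answer behaviour, gradual fatigue or learning, heterogeneous mood
reactivity across people, lapses and attention failures, and any
direct mood effect on response vigor. Passing tests therefore show the
pipeline is correct and well-calibrated on data satisfying the model's
own assumptions — not that real data satisfy them.

## Study drivers and their problem sizes

`run_sampling_comparison()` validates the adaptive sampler against
grid lattices (9–64 offers) and uniform random sampling: per simulated
agent it generates dummy choices under each sampler, refits the
generating model, and records balanced accuracy, mean posterior
variance and (across simulations) recovery correlations. Balanced
accuracy is computed on a *common probe set* per agent — the adaptive
sampler concentrates its training trials near indifference, where
choices are intrinsically unpredictable, so in-sample accuracy (also
reported) reflects trial difficulty rather than model quality. The
full-scale budget is the cube of the parameter count (13³ = 2197
mood-free, 14³ = 2744 with the mood weight); the package's validation
suites run 100 simulations at the 64-trial budget, which preserves the
qualitative comparisons at desk scale. For the mood-weight
recoverability study the simulated population uses
$\beta_{Mood} \sim N(0.614, 1.75)$ — the group mean and
between-subject spread implied by published group statistics for this
paradigm (a mean of 0.614 with $t(101) = 3.54$ gives
$sd = 0.614\sqrt{102}/3.54 \approx 1.75$); recoverability is a ratio
of population spread to estimation error, so it is only meaningful
against the population the tool is used on. Two fitting subtleties
matter here: the additive mood model has a reflected near-mode
(negating all biases and the mood weight preserves the
$\beta_0 \beta_{Mood}$ products that dominate when $|\beta_{Mood}|$
is large), so the fitter explicitly optimizes from the reflection of
its best solution; and the mood weight is unidentified when every
$\beta_0 \approx 0$, which the fitter warns about.

`analyze_mood_effects()` runs the model-free battery: episode
choice-rate contrasts, per-subject logistic regressions of choice on
rated mood, an RT model with choice × condition interaction on
filtered residuals (0.75 s < RT < 10 s, median ± 3 SD, session and
trial number regressed out), and within-episode slopes of the replayed
AUC trace (z-scored per session, interpolated across the 4-trial
cost-type cycle, time-on-task regressed out; first-episode order is
between-subject at cohort level and enters group summaries rather
than the within-subject regression). The AUC replay inherits the
sliding window's lag — a 20-choice window per cost type spans several
episodes of the 4-type trial cycle — so single-episode slopes are
blurred toward the surrounding transitions; the robust readout is the
within-subject difference between positive- and negative-episode
slopes. All group tests are two-tailed
one-sample/paired t-tests on per-subject statistics, no
multiple-testing correction, with the nominal alpha reported.

On the RT interaction's direction under this generator: because RT
falls with the chosen option's value advantage, a positive mood bias
extends costly choices into lower-advantage territory, making costly
choices *relatively slower* in positive episodes — a selection effect
with a positive interaction sign under non-adaptive sampling. The
adaptive sampler screens this off (it re-centres offers on the
shifted indifference point), leaving no stable interaction, so the
pipeline checks assert the constructed sign under non-adaptive
sampling.

A caveat on model-selection power with synthetic cohorts: a constant
softmax bias of around one logit unit shifts the indifference point
by about a euro, which 256 choices cannot distinguish from a
comparable adjustment of the discount weights — under adaptive and
random sampling alike, the per-subject evidence difference between
the full model and its bias-free reduction is then close to zero, and
random-effects selection splits between them. Discriminating
bias-present from bias-absent models sharply requires a population
whose biases are large relative to that trade-off, as real cohorts
selected by this model family evidently are. The
additive-versus-multiplicative mood arbitration does not suffer from
this: the two variants differ in how mood enters the likelihood
within a session, which is exactly the variation the design
manipulates — and for the same reason the mood weight itself is
recovered well even though the constant bias is not separately
pinned down.

## Known limitations

* The Laplace evidence is a local approximation; strongly multimodal
  posteriors (weak mood levers, temperature/weight trade-offs) are
  summarized by their dominant mode.
* Individual cost weights and the shared reward weight trade off near
  indifference; recovery is reliable for the mood weight and the
  curve, less so for single weights.
* The OTG fixed temperature is a convention; mismatch with a very
  noisy decision maker makes the online curve chase noise within its
  20-trial window.
* Exceedance probabilities are Monte-Carlo estimates (±0.005 at the
  default draw count); protected exceedance probabilities are out of
  scope.
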