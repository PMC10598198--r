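Package: moodchoice
Title: Mood-Modulated Cost-Benefit Choice Modelling with Online Trial
    Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how incidental mood shifts cost-benefit
    tradeoffs in economic decisions. Implements the Online Trial Generation
    (OTG) algorithm, a closed-loop adaptive procedure that maintains a
    piecewise-linear indifference curve per cost type (risk, delay, physical
    effort, mental effort) and samples each upcoming offer near the current
    indifference estimate; a family of discount/softmax choice models with
    an additive or multiplicative mood bias; MAP model inversion with a
    Laplace approximation to the model evidence; random-effects Bayesian
    model selection (expected frequencies and exceedance probabilities); a
    synthetic-agent simulator reproducing the probabilistic-feedback mood
    induction design; and study drivers comparing OTG against grid and
    random sampling on balanced accuracy, posterior variance, and
    parameter recoverability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
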