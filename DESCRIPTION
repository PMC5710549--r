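Package: moodfit
Title: Recency-Weighted Modelling of Momentary Mood in Risky Decision Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational modelling of momentary mood (happiness)
    during value-based decision tasks. Simulates three task variants (a
    laboratory risky decision task with intermittent happiness probes, a
    short smartphone variant, and a fully described probabilistic reward
    task), predicts momentary happiness from the recency-weighted history
    of certain rewards, gamble expected values and reward prediction
    errors, fits the model per participant by exhaustive search over the
    forgetting factor with closed-form least squares for the weights,
    compares alternative model families by a BIC approximation to model
    evidence, generates synthetic cohorts whose baseline mood parameter is
    linked to depression-severity scores, and provides the nonparametric
    group statistics (Wilcoxon tests, Spearman and covariate-residualized
    Spearman correlations) and participant-exclusion rules used to analyse
    such cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
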