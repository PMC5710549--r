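---
title: "Modelling momentary mood from rewards, expectations and prediction errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling momentary mood from rewards, expectations and prediction errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodfit)
library(dplyr)
```

## The model

During a risky decision task, participants intermittently report how happy
they feel on a bounded cursor-on-a-line scale. moodfit models the rating
collected after trial $t$ as a recency-weighted regression on the history of
three per-trial event values:

$$
\hat h(t) \;=\; w_0
\;+\; w_{CR}\sum_{j \le t}\gamma^{\,t-j}\,CR_j
\;+\; w_{EV}\sum_{j \le t}\gamma^{\,t-j}\,EV_j
\;+\; w_{RPE}\sum_{j \le t}\gamma^{\,t-j}\,RPE_j
$$

* $CR_j$ is the certain reward when the safe option was chosen on trial $j$;
* $EV_j$ is the expected value (probability-weighted average return) of a
  chosen gamble;
* $RPE_j$ is the reward prediction error, the experienced outcome minus
  $EV_j$, for a revealed gamble outcome;
* $\gamma \in [0,1]$ is a forgetting factor: recent events weigh more, with
  exponential decay;
* $w_0$ is the baseline mood parameter — the intercept that remains after
  task-driven fluctuations are accounted for. It is the quantity of clinical
  interest, because it can be related to depression-severity questionnaires
  (HAM-D, PHQ, BDI-II) measured on much longer time scales.

Two zeroing rules define the term series. Terms for unchosen options are
zero: a trial contributes to the $CR$ sum or to the $EV$ sum, never both.
And when a gamble's outcome is withheld, its RPE is zero — no surprise
occurred — while its EV term is kept, because the expectation was formed at
choice time.

Two alternative families are used for model comparison. The
*no-expectation* family drops the EV term. The *split-RPE* family replaces
$w_{RPE}\,RPE_j$ by $w_R\,R_j + w_{-EV}\,(-EV_j)$ on revealed gamble
trials, i.e. it splits the prediction error into its two components, the
received reward and the negated expectation. With $w_R = w_{-EV} = w_{RPE}$
the split family reproduces the full model exactly (a tested identity), so
the full model is nested between the two alternatives with 4, 5 and 6 free
parameters respectively (intercept, term weights, $\gamma$).

Ratings and predictions live on $[0,1]$ and are not standardized by
default: keeping $w_0$ on the common rating scale is what makes it
comparable across participants when correlating with symptom scores.

## The three task variants

* **Laboratory risky decision task** — 160 choice trials between a certain
  amount and a two-outcome gamble, with 66 happiness probes. Probes occur
  after every 2 to 3 trials; given the printed totals the gap multiset is
  forced (38 gaps of 2 and 28 of 3 solve $a+b=66$, $2a+3b=160$), so only
  the gap *order* is randomized, under the caller's seed. Outcomes are
  revealed on exactly half of the chosen gambles; the other half are
  banked unseen ("outcome added to total"), giving EV-only trials.
* **Smartphone variant** — 30 trials and 12 probes (6 gaps of 2, 6 of 3),
  equal-probability two-outcome spinners resolved immediately, and a
  starting endowment of 500 points.
* **Probabilistic reward task** — 164 scanner trials with no probes and no
  learning requirement: on each trial an "observation lottery" winning +£1
  or losing −£1 with fully described win probability 0%, 25%, 75% or 100%
  (levels balanced, 41 trials each) is paired with a statewise-dominated
  alternative, so a reward-maximizing agent always takes the observation
  lottery and errors are pure performance lapses. The per-trial EV (at
  choice) and RPE (at outcome) series — the parametric modulators used in
  neuroimaging analyses — take EV values $\{-1, -0.5, +0.5, +1\}$ and are
  `NA` on error trials.

The published task descriptions do not include the stake distributions of
the risky tasks, so these are configuration (`stake_defaults()`): 50/50
gambles whose high/low outcomes straddle the certain amount by a uniform
spread, pound-scale in the laboratory ($\pm$£1 certain range, spreads of
0.5–2) and point-scale on the smartphone ($\pm$50 points, spreads of
25–100). These were chosen once as plausible magnitudes; analyses in the
package do not depend on them beyond giving the regressors realistic
variance.

## Fitting and model comparison

Given $\gamma$, the model is linear in $(w_0, w)$, so `fit_mood_model()`
finds the global least-squares optimum by brute force over a fixed
$\gamma$ grid (step 0.01 over $[0,1]$, configurable) with the weights
solved in closed form by ordinary least squares at each grid point; exact
ties in the residual sum of squares go to the smaller $\gamma$. This is
deterministic, cheap (the decayed sums are a first-order recursive
filter), and — unlike gradient methods on the jointly nonconvex problem —
cannot be trapped locally. Weights are unbounded; the $[0,1]$ clipping of
the rating scale is a property of simulation, not of fitting. Goodness of
fit is $r^2 = 1 - SSE/TSS$; ratings with zero variance get the degenerate
convention $w_0 = \bar h$, zero weights, $r^2 = 0$, flagged.

Model families are compared with a Gaussian-likelihood BIC,
$n\ln(\max(SSE,\varepsilon)/n) + k\ln n$ with $\varepsilon = 10^{-12}$,
summed across participants (a fixed-effects comparison). This is a
standard desk-scale surrogate for model evidence; random-effects selection
(exceedance probabilities) is out of scope. The residual variance is not
counted in $k$ — it is common to all families and cannot alter a ranking.
Ties are reported, never broken silently.

## The synthetic cohort generator

`generate_cohort()` produces complete studies so every downstream stage is
testable without participant data. It emulates:

* **Symptom structure.** For laboratory cohorts, HAM-D and PHQ scores are
  drawn per group from truncated, rounded bivariate normals (correlation
  0.8) with the published group means/SDs as defaults (depressed ≈ 15.6
  (4.1) HAM-D / 15.8 (4.7) PHQ; controls 0.6 (1.0) / 1.1 (1.7)).
  Smartphone cohorts draw BDI-II from a two-component mixture (70% mild,
  mean 6 SD 5; 30% elevated, mean 20 SD 10, truncated to 0–63), with the
  conventional ≥15 cut labelling the high-severity group.
* **The linkage of interest.** Each participant's true baseline mood is
  $w_{0,i} = \alpha + \beta_s z_i + \varepsilon_i$ with $z_i$ the
  standardized symptom score. The defaults $\alpha = 0.5$,
  $\beta_s = -0.033$, $\mathrm{sd}(\varepsilon) = 0.1$ target a generating
  Spearman correlation of about $-0.3$, the magnitude reported in
  large-sample smartphone data; $\beta_s = 0$ gives a null cohort. All
  other weights are drawn independently of symptoms, so their symptom
  correlations are null by construction — mirroring the empirical finding
  that the emotional impact of RPEs is *not* reduced with severity.
* **Choices.** The tasks measure but do not model risk taking, so any
  generator with realistic gamble shares suffices; the simplest with a
  tunable risk preference is a logistic choice rule
  $P(\text{gamble}) = \sigma(b + \beta\,(EV - CR))$. Scanner performance
  uses a fixed accuracy (default 0.97, matching the near-ceiling rates the
  task is designed for), with "failure" participants at 0.7 — far enough
  below the >30-missed-trials exclusion threshold to make the excluded
  count deterministic in practice.
* **Ratings.** Model predictions plus i.i.d. Gaussian noise (default SD
  0.05 rating units), clipped to $[0,1]$. Clipping rather than truncated
  sampling keeps the generative model identical to the fitted one; the
  clipped fraction is attached to every session and a warning fires when
  it is nonzero (about 0.5% of probes under defaults) so users can keep it
  negligible.

What the generator does **not** emulate: real rating autocorrelation beyond
the model (e.g. drift, fatigue), heaped/discretized cursor placement,
reaction times, dropout, medication effects on parameters, or test–retest
dynamics. Passing recovery tests therefore shows the pipeline is correct
and well-conditioned at realistic sizes and noise — not that the model is
true of any particular dataset.

## Group statistics

The analysis toolkit is deliberately nonparametric, matching field
practice for skewed questionnaire data: Wilcoxon rank sum and signed rank
tests reporting tie-corrected $z$ statistics, and Spearman correlations,
all two-tailed with $\alpha = .05$ and no multiple-testing adjustment
(documented; mirroring the analysis convention it reproduces). Average
ranks handle ties throughout. Exact p-values by complete enumeration are
used below 9 observations (per group / nonzero differences); the normal
approximation without continuity correction is used above, which is also
exactly the standardization of the permutation distribution — the basis of
the package's oracle tests. Spearman p-values use the t approximation;
`residualized_spearman()` first removes covariates (age, sex, and
education as a university-degree indicator — entered dichotomously by
convention) from both variables by least squares and correlates the
residuals.

The exclusion filter removes participants who missed the observation
lottery on strictly more than 30 of 164 trials; applied to a simulated
35-participant scanned sample with 3 poor performers it yields the
analyzed sample of 32.

## Numerical choices and problem sizes

* $\gamma$ grid step 0.01; ties toward smaller $\gamma$; generating values
  placed on the grid recover exactly on noise-free data.
* BIC floor $\varepsilon = 10^{-12}$ keeps perfect fits finite.
* Aliased design columns (a term never instantiated in a session) get
  weight 0 rather than `NA`.
* Serialized ratings and money amounts use 6 fixed decimals, making
  pipeline outputs byte-reproducible from a seed and session files exact
  round-trips; parameter files use 17 significant digits and round-trip to
  the exact double.
* Child seeds for per-participant streams are derived from the caller's
  single seed with a fixed integer recurrence, so one seed pins the entire
  study.

The test and acceptance suites use sizes the package's authors consider
informative at desk scale: 100 replicates for weight recovery (median
absolute error per weight under 25% of its generating value at noise SD
0.05), 20 seeded cohorts of 50 participants per model-selection scenario,
and 10 smartphone cohorts of n = 1833 for linkage recovery (recovered
Spearman within 0.07 of the generating value), with the null-linkage check
at n = 600, where 3 standard errors of a null Spearman is ±0.12.

## Known limitations

* The model-evidence proxy is a BIC sum, not the full Bayesian
  random-effects machinery; with strongly heterogeneous participants the
  two can disagree.
* The forgetting factor is only weakly identified from 12-probe smartphone
  sessions; its per-participant estimates are noisy there (the baseline
  and weight estimates remain well-behaved, which is why linkage recovery
  succeeds).
* Only the two published alternative families are implemented;
  temporal-difference, loss-aversion and risk-weighted utility variants
  are out of scope.
* Heavy rating clipping (baselines near the scale ends with large swings)
  biases least-squares fits; the generator warns so such regimes are
  visible.
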