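# moodfit

Momentary mood — how happy someone says they are *right now* — fluctuates
during a gambling task, and those fluctuations are predictable from the
recent history of rewards, expectations, and the surprises in between.
moodfit implements that computational model of momentary mood together with
everything needed to study it at desk scale: simulators for the tasks it is
measured with, per-participant model fitting and model comparison, synthetic
cohorts whose baseline mood is linked to depression-severity questionnaires,
and the nonparametric group statistics used to analyse such cohorts. It is
aimed at computational-psychiatry researchers who want a tested, fully
reproducible pipeline for mood-dynamics analyses, power exploration and
parameter-recovery studies.

## The model

The happiness rating collected after trial $t$ is modelled as

$$
\hat h(t) = w_0
 + w_{CR}\sum_{j\le t}\gamma^{t-j} CR_j
 + w_{EV}\sum_{j\le t}\gamma^{t-j} EV_j
 + w_{RPE}\sum_{j\le t}\gamma^{t-j} RPE_j
$$

where $CR_j$ is the certain reward when the safe option was chosen, $EV_j$
the expected value of a chosen gamble, $RPE_j$ the reward prediction error
(outcome minus expectation) of a revealed gamble outcome, and
$\gamma\in[0,1]$ a forgetting factor giving recent events more influence.
Terms for unchosen options are zero, and the RPE is zero when the outcome is
not revealed. $w_0$, the baseline mood parameter, is the clinically
interesting quantity: it captures the persistent affective state left after
task-driven mood dynamics are modelled, and can be correlated with symptom
scales (HAM-D, PHQ, BDI-II). Alternative families omitting the expectation
term or splitting the RPE into its reward and negated-expectation components
are fitted for model comparison via a BIC approximation to model evidence.

Three task variants are simulated: the laboratory risky decision task (160
choice trials, 66 happiness probes every 2–3 trials, outcomes hidden on half
of the gamble choices), its smartphone variant (30 trials, 12 probes,
500-point endowment, equal-probability spinners), and the 164-trial
probabilistic reward task (±£1 lotteries with fully described 0/25/75/100%
win probabilities, no learning requirement) that supplies the per-trial EV
and RPE regressor series used in neuroimaging analyses.

## Worked example

Simulate one laboratory participant with known parameters and fit the model:

```r
library(moodfit)

session <- build_risky_session("lab", seed = 1) |>
  simulate_choices(seed = 2) |>
  simulate_ratings(mood_params(w0 = 0.5, w_cr = 0.1, w_ev = 0.1,
                               w_rpe = 0.1, gamma = 0.5),
                   noise_sd = 0.05, seed = 3)

fit <- fit_mood_model(session)
fit
#> <mood_fit> family 'full': r2 = 0.840, gamma = 0.48, BIC = -390.9 (n = 66 probes)
#>     w0     cr     ev    rpe
#> 0.4984 0.0940 0.0933 0.0977
```

The fitted weights land within a few thousandths of the generating values
(0.5, 0.1, 0.1, 0.1), the forgetting factor within grid resolution of the
generating 0.5, and the model explains 84% of rating variance at this noise
level; with noise-free ratings recovery is exact and `r2 = 1`. `tidy(fit)`,
`glance(fit)` and `autoplot(fit)` give the coefficient table, one-row fit
summary and an observed-vs-fitted probe plot.

Cohort-level analyses chain the same way:

```r
cohort <- generate_cohort(cohort_config("smartphone", n = 500), seed = 1)
fits   <- fit_cohort(cohort, specs = "full")
spearman_test(fits$w0, cohort$symptom)   # negative: lower baseline mood
                                         # with worse symptoms
compare_models(fit_cohort(cohort))       # BIC-summed family comparison
```

`replicate_study()` runs the whole pipeline — simulate, write session files,
fit all families, compare, compute group statistics — into a directory with
a JSON manifest; identical config and seed reproduce byte-identical tables.
A thin command-line wrapper (`exec/moodfit`) exposes `simulate-session`,
`simulate-cohort`, `fit`, `compare-models`, `cohort-stats` and `replicate`
subcommands.

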