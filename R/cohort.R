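#' Configuration for a synthetic cohort
#'
#' Describes a complete synthetic study: group sizes, symptom-score
#' distributions (defaults follow the published group summaries: depressed
#' participants with clinician-rated severity around 15.6 (SD 4.1) on the
#' HAM-D and 15.8 (SD 4.7) on the PHQ against near-zero control means;
#' smartphone self-report BDI-II scores from a two-component mixture
#' spanning the 0-63 range), the linkage between the baseline mood
#' parameter and symptom severity, the distributions of the remaining
#' model parameters, and the choice/stake/noise settings of the task.
#'
#' The baseline mood parameter of participant i is drawn as
#' `w0_i = w0_mean + beta_s * z_i + eps_i`, with `z_i` the participant's
#' standardized symptom score and `eps_i ~ N(0, w0_resid_sd)`. The default
#' `beta_s`/`w0_resid_sd` pair targets a generating Spearman correlation of
#' about -0.3 between baseline mood and symptoms, the magnitude seen in
#' large-sample data; set `beta_s = 0` for a null cohort. Other weights are
#' drawn independently of symptoms (so their symptom correlations are null
#' by construction).
#'
#' @param variant `"lab"` (two diagnosed groups, HAM-D/PHQ scores) or
#'   `"smartphone"` (one population with BDI-II scores).
#' @param n_mdd,n_control Group sizes for the lab variant.
#' @param n Population size for the smartphone variant.
#' @param beta_s Linkage slope, rating units per symptom SD (negative:
#'   worse symptoms, lower baseline mood).
#' @param w0_mean,w0_resid_sd Mean and residual SD of the baseline mood
#'   parameter.
#' @param weight_mean,weight_sd Mean and SD of the positive CR/EV/RPE
#'   weights (rating units per money unit; scaled to the variant's stakes).
#'   Either a scalar shared by the three weights or a length-3 vector in
#'   the order (CR, EV, RPE) — e.g. a zero EV entry generates data from
#'   the no-expectation family.
#' @param gamma_mean,gamma_sd Mean and SD of the forgetting factor
#'   (clipped to \[0, 1\]).
#' @param rating_noise_sd Rating noise SD.
#' @param hamd_mdd,hamd_control,phq_mdd,phq_control `c(mean, sd)` for the
#'   lab symptom scores; `hamd_phq_cor` their within-group correlation.
#' @param bdi_components Mixture for smartphone BDI-II scores: a list of
#'   `c(weight, mean, sd)` rows.
#' @param age,education `c(mean, sd)` of covariates; `prop_female`,
#'   `prop_medicated` group proportions.
#' @param stakes,choice Task settings, see [stake_defaults()] and
#'   [choice_defaults()].
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(variant = c("lab", "smartphone"),
                          n_mdd = 54, n_control = 20, n = 1833,
                          beta_s = -0.033, w0_mean = 0.5, w0_resid_sd = 0.1,
                          weight_mean = NULL, weight_sd = NULL,
                          gamma_mean = 0.4, gamma_sd = 0.15,
                          rating_noise_sd = 0.05,
                          hamd_mdd = c(15.6, 4.1), hamd_control = c(0.6, 1.0),
                          phq_mdd = c(15.8, 4.7), phq_control = c(1.1, 1.7),
                          hamd_phq_cor = 0.8,
                          bdi_components = list(c(0.7, 6, 5), c(0.3, 20, 10)),
                          age = c(34.3, 11.1), education = c(16.3, 2.2),
                          prop_female = 0.6, prop_medicated = 0.61,
                          stakes = stake_defaults(variant),
                          choice = choice_defaults(variant)) {
  variant <- match.arg(variant)
  scale <- if (variant == "lab") 1 else 1 / 50 # points vs pounds
  structure(
    list(variant = variant, n_mdd = n_mdd, n_control = n_control, n = n,
         beta_s = beta_s, w0_mean = w0_mean, w0_resid_sd = w0_resid_sd,
         weight_mean = weight_mean %||% (0.1 * scale),
         weight_sd = weight_sd %||% (0.03 * scale),
         gamma_mean = gamma_mean, gamma_sd = gamma_sd,
         rating_noise_sd = rating_noise_sd,
         hamd_mdd = hamd_mdd, hamd_control = hamd_control,
         phq_mdd = phq_mdd, phq_control = phq_control,
         hamd_phq_cor = hamd_phq_cor, bdi_components = bdi_components,
         age = age, education = education, prop_female = prop_female,
         prop_medicated = prop_medicated, stakes = stakes, choice = choice),
    class = "cohort_config"
  )
}

# Correlated pair of truncated, rounded questionnaire scores.
draw_scores <- function(n, m1, m2, rho, max1, max2) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  s1 <- round(pmin(pmax(m1[1] + m1[2] * z1, 0), max1))
  s2 <- round(pmin(pmax(m2[1] + m2[2] * z2, 0), max2))
  cbind(s1, s2)
}

draw_bdi <- function(n, components) {
  w <- vapply(components, `[`, numeric(1), 1)
  pick <- sample.int(length(components), n, replace = TRUE, prob = w)
  mu <- vapply(components, `[`, numeric(1), 2)[pick]
  sd <- vapply(components, `[`, numeric(1), 3)[pick]
  round(pmin(pmax(rnorm(n, mu, sd), 0), 63))
}

#' Generate a complete synthetic cohort
#'
#' Draws participants (group labels, symptom scores, covariates), their
#' true momentary-mood parameters — with the baseline mood parameter
#' linked to standardized symptom severity by the configured slope — and a
#' simulated session with choices, outcomes and noisy happiness ratings
#' for each participant.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed governing every random draw.
#' @return A `mood_cohort` tibble: one row per participant with metadata,
#'   true parameters, the session as a list column and the fraction of
#'   clipped ratings. The configuration is attached as an attribute.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  n_total <- if (config$variant == "lab") {
    config$n_mdd + config$n_control
  } else {
    config$n
  }
  if (n_total <= 0) {
    abort("Cohort configuration requests zero participants.")
  }
  meta <- with_seed(child_seed(seed, 1L), draw_metadata(config, n_total))
  params <- with_seed(child_seed(seed, 2L), draw_params(config, meta))
  cohort <- dplyr::bind_cols(meta, params)

  sessions <- purrr::map(seq_len(n_total), function(i) {
    s <- build_risky_session(config$variant, seed = child_seed(seed, 100L + i),
                             stakes = config$stakes)
    s <- simulate_choices(s, choice = config$choice,
                          seed = child_seed(seed, 200000L + i))
    p <- mood_params(w0 = cohort$w0[i], w_cr = cohort$w_cr[i],
                     w_ev = cohort$w_ev[i], w_rpe = cohort$w_rpe[i],
                     gamma = cohort$gamma[i])
    suppressWarnings(
      simulate_ratings(s, p, noise_sd = config$rating_noise_sd,
                       seed = child_seed(seed, 400000L + i))
    )
  })
  cohort$session <- sessions
  cohort$clip_fraction <- vapply(sessions, attr, numeric(1), "clip_fraction")
  total_clip <- mean(cohort$clip_fraction)
  if (total_clip > 0.01) {
    warn(sprintf("%.1f%% of all simulated ratings were clipped to [0, 1].",
                 100 * total_clip))
  }
  attr(cohort, "config") <- config
  class(cohort) <- c("mood_cohort", class(cohort))
  cohort
}

draw_metadata <- function(config, n_total) {
  if (config$variant == "lab") {
    group <- rep(c("MDD", "control"), c(config$n_mdd, config$n_control))
    s_mdd <- draw_scores(config$n_mdd, config$hamd_mdd, config$phq_mdd,
                         config$hamd_phq_cor, 52, 27)
    s_ctl <- draw_scores(config$n_control, config$hamd_control,
                         config$phq_control, config$hamd_phq_cor, 52, 27)
    hamd <- c(s_mdd[, 1], s_ctl[, 1])
    phq <- c(s_mdd[, 2], s_ctl[, 2])
    bdi <- rep(NA_real_, n_total)
    symptom <- hamd
    anhedonia <- round(pmin(pmax(phq / 9 + rnorm(n_total, 0, 0.5), 0), 3))
    medicated <- ifelse(group == "MDD",
                        runif(n_total) < config$prop_medicated, FALSE)
  } else {
    bdi <- draw_bdi(n_total, config$bdi_components)
    group <- ifelse(bdi >= 15, "MDD", "control") # high/low severity split
    hamd <- rep(NA_real_, n_total)
    phq <- rep(NA_real_, n_total)
    symptom <- bdi
    anhedonia <- round(pmin(pmax(0.2 * bdi + rnorm(n_total, 0, 1), 0), 12))
    medicated <- runif(n_total) < 0.3
  }
  education <- pmax(round(rnorm(n_total, config$education[1],
                                config$education[2])), 8)
  tibble(
    participant = sprintf("P%04d", seq_len(n_total)),
    group = group, hamd = hamd, phq = phq, bdi = bdi, symptom = symptom,
    anhedonia = anhedonia, medicated = medicated,
    age = pmax(round(rnorm(n_total, config$age[1], config$age[2])), 18),
    sex = sample(c("F", "M"), n_total, replace = TRUE,
                 prob = c(config$prop_female, 1 - config$prop_female)),
    education_years = education,
    degree = education >= 16 # university degree indicator
  )
}

draw_params <- function(config, meta) {
  n <- nrow(meta)
  z <- as.numeric(scale(meta$symptom))
  if (any(!is.finite(z))) z <- rep(0, n) # constant symptom scores
  wm <- rep_len(config$weight_mean, 3)
  ws <- rep_len(config$weight_sd, 3)
  draw_w <- function(m, s) if (m == 0 && s == 0) rep(0, n) else pmax(rnorm(n, m, s), 0)
  tibble(
    w0 = config$w0_mean + config$beta_s * z + rnorm(n, 0, config$w0_resid_sd),
    w_cr = draw_w(wm[1], ws[1]),
    w_ev = draw_w(wm[2], ws[2]),
    w_rpe = draw_w(wm[3], ws[3]),
    gamma = pmin(pmax(rnorm(n, config$gamma_mean, config$gamma_sd), 0), 1)
  )
}

#' Fit every participant of a cohort under one or more model families
#'
#' @param cohort A `mood_cohort` (or any tibble with `participant` and
#'   `session` columns).
#' @param specs Model family ids to fit (default: all).
#' @param gamma_grid Forgetting-factor grid passed to [fit_mood_model()].
#' @return A tidy fit table: one row per participant and family with the
#'   fitted parameters (`w0`, `w_cr`, `w_ev`, `w_rpe`, `w_r`, `w_negev`,
#'   `gamma`; families that lack a term leave it `NA`), `r2`, `sse`,
#'   `n_probes`, `k_params` and `ic`.
#' @export
fit_cohort <- function(cohort, specs = model_specs(),
                       gamma_grid = seq(0, 1, by = 0.01)) {
  all_weights <- c("w_cr", "w_ev", "w_rpe", "w_r", "w_negev")
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    purrr::map(specs, function(sp) {
      f <- fit_mood_model(cohort$session[[i]], spec = sp,
                          gamma_grid = gamma_grid)
      est <- setNames(rep(NA_real_, length(all_weights)), all_weights)
      got <- unlist(f$params[model_terms(sp)])
      est[names(got)] <- got
      dplyr::bind_cols(
        tibble(participant = cohort$participant[i], spec = sp,
               w0 = f$params$w0),
        as_tibble(as.list(est)),
        tibble(gamma = f$gamma, r2 = f$r2, sse = f$sse,
               n_probes = f$n_probes, k_params = f$k_params, ic = f$ic,
               zero_variance = f$zero_variance)
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Simulate the scanned probabilistic-task sample
#'
#' Builds one probabilistic session per participant and simulates choices
#' with a per-participant accuracy: most participants choose the
#' observation lottery with high probability while `n_fail` "failure"
#' participants perform poorly enough to miss it on well over 30 trials,
#' emulating the performance-based exclusion scenario.
#'
#' @param n Number of scanned participants.
#' @param n_fail Number of poorly performing participants.
#' @param accuracy_ok,accuracy_fail Observation-lottery choice
#'   probabilities for the two performance levels.
#' @param seed Integer seed.
#' @return A tibble with `participant`, `accuracy`, `n_missed` (trials
#'   where the observation lottery was not chosen) and the `session` list
#'   column.
#' @export
generate_scanned_sample <- function(n = 35, n_fail = 3, accuracy_ok = 0.97,
                                    accuracy_fail = 0.7, seed = NULL) {
  accuracy <- c(rep(accuracy_fail, n_fail), rep(accuracy_ok, n - n_fail))
  sessions <- purrr::map(seq_len(n), function(i) {
    s <- build_probabilistic_session(seed = child_seed(seed, i))
    simulate_choices(s, choice = list(accuracy = accuracy[i]),
                     seed = child_seed(seed, 1000L + i))
  })
  tibble(
    participant = sprintf("S%03d", seq_len(n)),
    accuracy = accuracy,
    n_missed = vapply(sessions, function(s) sum(s$choice != "observation"),
                      numeric(1)),
    session = sessions
  )
}
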