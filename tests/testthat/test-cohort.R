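test_that("a value-maximizing agent always gambles when the gamble dominates", {
  s <- build_risky_session("lab", seed = 1)
  s$gamble_hi <- s$certain_amount + 2
  s$gamble_lo <- s$certain_amount + 1 # EV always above CR
  s <- simulate_choices(s, choice = list(beta = Inf, bias = 0), seed = 2)
  expect_true(all(s$choice == "gamble"))
})

test_that("a bias-only agent gambles on half the trials (binomial check)", {
  s <- build_risky_session("lab", seed = 3, n_trials = 9999, n_probes = 3333)
  s <- simulate_choices(s, choice = list(beta = 0, bias = 0), seed = 4)
  share <- mean(s$choice == "gamble")
  se <- sqrt(0.25 / nrow(s))
  expect_lt(abs(share - 0.5), 3 * se)
})

test_that("exactly half of chosen gambles in the lab task stay unrevealed", {
  for (seed in 1:5) {
    s <- simulate_choices(build_risky_session("lab", seed = seed),
                          seed = seed + 100)
    n_gamble <- sum(s$choice == "gamble")
    expect_equal(sum(s$choice == "gamble" & !s$revealed),
                 floor(n_gamble / 2))
    expect_true(all(s$revealed[s$choice == "certain"]))
  }
})

test_that("noiseless ratings equal predictions; residual noise has the requested sd", {
  p <- mood_params(0.5, 0.05, 0.05, 0.05, gamma = 0.5)
  s <- simulate_choices(build_risky_session("lab", seed = 5), seed = 6)
  exact <- simulate_ratings(s, p, noise_sd = 0, seed = 7)
  expect_equal(exact$rating[exact$probe],
               predict_happiness(s, p)$prediction)
  expect_equal(attr(exact, "clip_fraction"), 0)

  # ~1000 probes across many probe-rich sessions
  long <- build_risky_session("lab", seed = 8, n_trials = 2500,
                              n_probes = 1000)
  long <- simulate_choices(long, seed = 9)
  calm <- mood_params(0.5, 0.005, 0.005, 0.005, gamma = 0.3)
  noisy <- simulate_ratings(long, calm, noise_sd = 0.05, seed = 10)
  res <- noisy$rating[noisy$probe] - predict_happiness(long, calm)$prediction
  expect_lt(abs(sd(res) - 0.05) / 0.05, 0.10)
})

test_that("out-of-scale baselines clip to the rating bounds with a warning", {
  s <- simulate_choices(build_risky_session("smartphone", seed = 11),
                        seed = 12)
  p <- mood_params(w0 = 1.5, gamma = 0.5)
  expect_warning(r <- simulate_ratings(s, p, noise_sd = 0, seed = 13),
                 "clipped")
  expect_true(all(r$rating[r$probe] == 1))
  expect_equal(attr(r, "clip_fraction"), 1)
})

test_that("lab cohorts separate symptom scores between groups", {
  for (seed in 1:3) {
    cfg <- cohort_config("lab", n_mdd = 15, n_control = 12)
    co <- generate_cohort(cfg, seed = seed)
    expect_true(all(co$hamd >= 0 & co$hamd <= 52))
    expect_true(all(co$phq >= 0 & co$phq <= 27))
    rs <- ranksum_test(co$symptom[co$group == "MDD"],
                       co$symptom[co$group == "control"])
    expect_lt(rs$p_value, 0.05)
    expect_gt(rs$estimate, 0)
  }
  # HAM-D and PHQ move together
  co <- generate_cohort(cohort_config("lab"), seed = 9)
  expect_gt(cor(co$hamd, co$phq), 0.5)
})

test_that("null symptom linkage gives a null w0 correlation", {
  cfg <- cohort_config("smartphone", n = 300, beta_s = 0)
  co <- generate_cohort(cfg, seed = 21)
  rho <- spearman_test(co$w0, co$symptom)$estimate
  expect_lt(abs(rho), 3 / sqrt(nrow(co) - 1))
})

test_that("the RPE weight is drawn independently of symptoms", {
  co <- generate_cohort(cohort_config("smartphone", n = 300), seed = 22)
  rho <- spearman_test(co$w_rpe, co$symptom)$estimate
  expect_lt(abs(rho), 3 / sqrt(nrow(co) - 1))
})

test_that("an empty cohort configuration is rejected", {
  expect_error(generate_cohort(cohort_config("smartphone", n = 0)),
               "zero participants")
})

test_that("fitting a generated cohort recovers weights without systematic bias", {
  co <- generate_cohort(cohort_config("lab", n_mdd = 25, n_control = 15),
                        seed = 31)
  fits <- fit_cohort(co, specs = "full")
  for (w in c("w_cr", "w_ev", "w_rpe")) {
    err <- fits[[w]] - co[[w]]
    bt <- stats::binom.test(sum(err > 0), length(err))
    expect_gt(bt$p.value, 0.05)
  }
})

test_that("mean recovered r2 decreases as rating noise grows", {
  mean_r2 <- vapply(c(0, 0.05, 0.1, 0.2), function(noise) {
    cfg <- cohort_config("lab", n_mdd = 5, n_control = 3,
                         rating_noise_sd = noise)
    co <- suppressWarnings(generate_cohort(cfg, seed = 41)) # sd 0.2 clips

    mean(fit_cohort(co, specs = "full")$r2)
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})

test_that("the scanned sample exclusion reproduces the analyzed-n boundary", {
  sample35 <- generate_scanned_sample(n = 35, n_fail = 3, seed = 51)
  expect_equal(sum(sample35$n_missed > 30), 3)
  kept <- suppressMessages(apply_exclusion(sample35))
  expect_equal(nrow(kept), 32)
  expect_length(attr(kept, "excluded"), 3)
})
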