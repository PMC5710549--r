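gen <- mood_params(w0 = 0.5, w_cr = 0.1, w_ev = 0.1, w_rpe = 0.1,
                   gamma = 0.5)

test_that("noise-free ratings recover the generating parameters exactly", {
  s <- simulated_participant(gen, noise_sd = 0, seed = 1)
  f <- fit_mood_model(s)
  expect_equal(f$params$w0, 0.5, tolerance = 1e-6)
  expect_equal(f$params$w_cr, 0.1, tolerance = 1e-6)
  expect_equal(f$params$w_ev, 0.1, tolerance = 1e-6)
  expect_equal(f$params$w_rpe, 0.1, tolerance = 1e-6)
  expect_equal(f$gamma, 0.5) # generating gamma lies on the grid
  expect_equal(f$r2, 1, tolerance = 1e-9)
})

test_that("constant ratings trigger the zero-variance convention", {
  s <- simulated_participant(gen, noise_sd = 0, seed = 2)
  s$rating[s$probe] <- 0.5
  expect_warning(f <- fit_mood_model(s), "zero variance")
  expect_equal(f$params$w0, 0.5)
  expect_equal(unname(f$coefficients[-1]), rep(0, 3))
  expect_equal(f$r2, 0)
  expect_true(f$zero_variance)
})

test_that("a fit with fewer rated probes than parameters is refused", {
  s <- simulated_participant(gen, noise_sd = 0, seed = 3)
  s$rating[s$probe][-(1:3)] <- NA
  expect_error(fit_mood_model(s), "Underdetermined")
})

test_that("the information criterion follows its algebra", {
  base <- information_criterion(0.2, 66, 5)
  expect_equal(information_criterion(0.1, 66, 5), base - 66 * log(2))
  expect_equal(information_criterion(0.2, 66, 6), base + log(66))
  # a substantially better fit justifies one extra parameter here
  expect_lt(information_criterion(0.165, 66, 5),
            information_criterion(0.25, 66, 4))
  expect_error(information_criterion(-1, 66, 5), "non-negative")
  expect_error(information_criterion(0.1, 0, 5), "positive")
})

test_that("grid search agrees with a brute-force 2-d scan on a small instance", {
  s <- build_risky_session("smartphone", seed = 4)
  s <- simulate_choices(s, seed = 5)
  p <- mood_params(0.5, 0.002, 0.002, 0.002, gamma = 0.4)
  s <- simulate_ratings(s, p, noise_sd = 0.02, seed = 6)
  f <- fit_mood_model(s)

  # oracle: scan gamma x w_cr densely, profiling the remaining weights by
  # least squares on the partial residual
  y <- s$rating[s$probe]
  probes <- which(s$probe)
  best <- list(sse = Inf, gamma = NA)
  for (g in seq(0, 1, by = 0.01)) {
    x_cr <- vapply(probes, function(t) oracle_decayed_sum(s$cr, t, g),
                   numeric(1))
    x_ev <- vapply(probes, function(t) oracle_decayed_sum(s$ev, t, g),
                   numeric(1))
    x_rpe <- vapply(probes, function(t) oracle_decayed_sum(s$rpe, t, g),
                    numeric(1))
    for (w_cr in seq(-0.002, 0.006, by = 0.0002)) {
      r <- lm(I(y - w_cr * x_cr) ~ x_ev + x_rpe)
      sse <- sum(resid(r)^2)
      if (sse < best$sse) best <- list(sse = sse, gamma = g)
    }
  }
  expect_equal(f$gamma, best$gamma, tolerance = 0.011)
  expect_lte(f$sse, best$sse + 1e-10)
})

test_that("r2 is invariant to rescaling the money units", {
  s <- simulated_participant(gen, noise_sd = 0.05, seed = 7)
  f1 <- fit_mood_model(s)
  scaled <- s
  for (col in c("certain_amount", "gamble_hi", "gamble_lo", "outcome",
                "cr", "ev", "rpe")) {
    scaled[[col]] <- scaled[[col]] * 100
  }
  f2 <- fit_mood_model(scaled)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-9)
  expect_equal(f2$params$w_cr, f1$params$w_cr / 100, tolerance = 1e-9)
})

test_that("tidy and glance return well-formed tibbles", {
  f <- fit_mood_model(simulated_participant(gen, noise_sd = 0.05, seed = 8))
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term[1], "w0")
  gl <- glance(f)
  expect_equal(gl$k_params, 5L)
  expect_equal(gl$n_probes, 66L)
})

test_that("model comparison sums the criterion and reports ties", {
  fits <- tibble::tibble(
    participant = rep(c("a", "b"), each = 2),
    spec = rep(c("full", "no_expectation"), 2),
    ic = c(-10, -8, -7, -8)
  )
  mc <- compare_models(fits)
  expect_equal(mc$summary$total_ic[mc$summary$spec == "full"], -17)
  expect_equal(mc$winner, "full")
  expect_false(mc$tie)
  expect_equal(mc$summary$n_best[mc$summary$spec == "full"], 1)

  tie <- tibble::tibble(participant = "a", spec = c("full", "split_rpe"),
                        ic = c(-5, -5))
  mct <- compare_models(tie)
  expect_true(mct$tie)
  expect_setequal(mct$winner, c("full", "split_rpe"))

  expect_error(
    compare_models(fits[-2, ]),
    "a x no_expectation"
  )
})
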