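test_that("spearman matches hand examples and the rank-then-Pearson oracle", {
  expect_equal(spearman_test(c(1, 2, 3), c(2, 4, 6))$estimate, 1)
  expect_equal(spearman_test(c(1, 2, 3), c(3, 1, 2))$estimate, -0.5)

  withr::with_seed(7, {
    for (i in 1:30) {
      n <- sample(4:12, 1)
      x <- sample(1:5, n, replace = TRUE) # duplicates guaranteed possible
      y <- rnorm(n)
      if (sd(x) == 0) next
      expect_equal(spearman_test(x, y)$estimate, oracle_spearman(x, y),
                   tolerance = 1e-12)
    }
  })
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:2, 2:1), "at least 3")
})

test_that("spearman is invariant under strictly monotone transforms", {
  withr::with_seed(8, {
    x <- rnorm(30); y <- rnorm(30)
    base <- spearman_test(x, y)$estimate
    expect_equal(spearman_test(exp(x), y)$estimate, base, tolerance = 1e-12)
    expect_equal(spearman_test(x, y^3 + 2 * y)$estimate, base,
                 tolerance = 1e-12)
  })
})

test_that("spearman agrees with cor.test on rho", {
  withr::with_seed(9, {
    x <- rnorm(40); y <- x + rnorm(40)
    ours <- spearman_test(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(ours$estimate, unname(ref$estimate), tolerance = 1e-12)
  })
})

test_that("rank tests match exhaustive permutation oracles at small n", {
  withr::with_seed(10, {
    for (i in 1:20) {
      n_a <- sample(2:7, 1); n_b <- sample(2:7, 1)
      a <- sample(1:6, n_a, replace = TRUE) + runif(n_a, 0, 0.01)
      b <- sample(1:6, n_b, replace = TRUE) + runif(n_b, 0, 0.01)
      ours <- ranksum_test(a, b)
      orac <- oracle_ranksum(a, b)
      expect_equal(ours$estimate, orac$z, tolerance = 1e-6)
      expect_equal(ours$p_value, orac$p, tolerance = 1e-12)
    }
    for (i in 1:15) {
      d <- rnorm(sample(3:8, 1))
      ours <- signedrank_test(d)
      orac <- oracle_signedrank(d)
      expect_equal(ours$estimate, orac$z, tolerance = 1e-6)
      expect_equal(ours$p_value, orac$p, tolerance = 1e-12)
    }
  })
})

test_that("rank sum handles symmetry, separation and large-sample reference", {
  same <- ranksum_test(1:9, 1:9)
  expect_equal(same$estimate, 0)
  expect_equal(same$p_value, 1)

  sep <- ranksum_test(1:10, 11:20)
  orac <- oracle_ranksum(1:10, 11:20)
  expect_equal(sep$estimate, orac$z, tolerance = 1e-6)
  expect_lt(sep$estimate, 0) # group a ranks lower

  # z sign agrees with the difference in mean ranks
  withr::with_seed(11, {
    a <- rnorm(15, 1); b <- rnorm(12)
    r <- rank(c(a, b))
    sign_ranks <- sign(mean(r[1:15]) - mean(r[-(1:15)]))
    expect_equal(sign(ranksum_test(a, b)$estimate), sign_ranks)
    # normal-approximation p agrees with wilcox.test's
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(ranksum_test(a, b)$p_value, ref$p.value, tolerance = 1e-9)
  })
})

test_that("signed rank follows the exact small-n conventions", {
  one <- signedrank_test(0.7)
  expect_equal(one$p_value, 1) # a single pair can never reach significance
  expect_error(signedrank_test(rep(0, 4)), "degenerate")
  withr::with_seed(12, {
    d <- rnorm(30, 0.5)
    ref <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)
    expect_equal(signedrank_test(d)$p_value, ref$p.value, tolerance = 1e-9)
  })
})

test_that("residualizing covariates behaves as a partial correlation", {
  withr::with_seed(13, {
    n <- 400
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    cov_orth <- data.frame(a = rnorm(n), b = runif(n) > 0.5)
    plain <- spearman_test(x, y)$estimate
    adj <- residualized_spearman(x, y, cov_orth)$estimate
    expect_lt(abs(adj - plain), 3 / sqrt(n - 1))

    # y exactly equal to a covariate is fully absorbed
    covs <- data.frame(age = rnorm(n))
    absorbed <- residualized_spearman(x, covs$age, covs)$estimate
    expect_lt(abs(absorbed), 3 / sqrt(n - 1))
  })
})

test_that("residualizing a shared confound shrinks the correlation", {
  shrunk <- withr::with_seed(14, {
    vapply(1:100, function(i) {
      n <- 120
      age <- rnorm(n)
      x <- age + rnorm(n, 0, 0.8)
      y <- age + rnorm(n, 0, 0.8)
      raw <- spearman_test(x, y)$estimate
      adj <- residualized_spearman(x, y, data.frame(age = age))$estimate
      abs(adj) < abs(raw)
    }, logical(1))
  })
  expect_gte(mean(shrunk), 0.90)
})

test_that("collinear covariates are refused with the offending column named", {
  withr::with_seed(15, {
    n <- 50
    covs <- data.frame(age = rnorm(n))
    covs$age2 <- 2 * covs$age
    expect_error(residualized_spearman(rnorm(n), rnorm(n), covs),
                 "Collinear.*age2")
  })
})

test_that("the exclusion filter uses a strict threshold", {
  d <- tibble::tibble(participant = c("a", "b", "c"),
                      n_missed = c(0, 30, 31))
  kept <- suppressMessages(apply_exclusion(d))
  expect_equal(kept$participant, c("a", "b"))
  expect_equal(attr(kept, "excluded"), "c")

  empty <- d[0, ]
  expect_equal(nrow(suppressMessages(apply_exclusion(empty))), 0)
  expect_error(apply_exclusion(d, missed = c(-1, 0, 0)), "negative")
})
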