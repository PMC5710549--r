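new_stat_result <- function(statistic, estimate, p_value, n,
                            covariates = NA_character_) {
  tibble(statistic = statistic, estimate = estimate, p_value = p_value,
         n = n, covariates = covariates)
}

drop_incomplete <- function(...) {
  d <- tibble(...)
  d[complete.cases(d), , drop = FALSE]
}

#' Spearman rank correlation with a two-tailed p value
#'
#' Rank correlation using average ranks for ties; the p value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom, two-tailed.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values
#'   are dropped); at least 3 complete pairs, neither constant.
#' @return A one-row tibble: `statistic`, `estimate` (rho), `p_value`,
#'   `n`, `covariates`.
#' @examples
#' spearman_test(c(1, 2, 3), c(3, 1, 2)) # rho = -0.5
#' @export
spearman_test <- function(x, y) {
  d <- drop_incomplete(x = x, y = y)
  n <- nrow(d)
  if (n < 3) abort("Spearman correlation needs at least 3 complete pairs.")
  if (sd(d$x) == 0 || sd(d$y) == 0) {
    abort("Spearman correlation is undefined for constant input.")
  }
  rho <- cor(rank(d$x), rank(d$y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  new_stat_result("spearman", rho, min(p, 1), n)
}

#' Spearman correlation after regressing out covariates
#'
#' Both variables are residualized on the covariates (plus an intercept)
#' by ordinary least squares, and the Spearman correlation of the
#' residuals is returned. Logical covariates (e.g. a university-degree
#' indicator) enter as 0/1; character/factor covariates are expanded to
#' indicator columns.
#'
#' @param x,y Numeric vectors.
#' @param covariates A data frame of covariates, same length as `x`.
#' @return A one-row tibble as in [spearman_test()], with the covariate
#'   names recorded.
#' @export
residualized_spearman <- function(x, y, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(x)) {
    abort("`covariates` must have one row per observation.")
  }
  keep <- complete.cases(x, y, covariates)
  x <- x[keep]; y <- y[keep]
  covariates <- covariates[keep, , drop = FALSE]
  M <- stats::model.matrix(~ ., data = covariates)
  q <- qr(M)
  if (q$rank < ncol(M)) {
    collinear <- colnames(M)[setdiff(seq_len(ncol(M)), q$pivot[seq_len(q$rank)])]
    abort(sprintf("Collinear covariate column(s): %s.",
                  paste(collinear, collapse = ", ")))
  }
  rx <- stats::lm.fit(M, x)$residuals
  ry <- stats::lm.fit(M, y)$residuals
  out <- spearman_test(rx, ry)
  out$statistic <- "spearman_residualized"
  out$covariates <- paste(colnames(covariates), collapse = "+")
  out
}

# Rank-based tests report the normal-approximation z statistic with a tie
# correction; for small samples the p value comes from the exact
# permutation distribution instead of the normal tail.
exact_cutoff <- 9L

#' Wilcoxon rank sum test (two independent groups)
#'
#' Reports the tie-corrected z statistic (positive when `a` tends to rank
#' higher than `b`) and a two-tailed p value: exact by complete
#' enumeration of group assignments when both groups have fewer than 9
#' observations, otherwise from the normal approximation.
#'
#' @param a,b Numeric samples.
#' @return A one-row tibble: `statistic`, `estimate` (z), `p_value`, `n`.
#' @export
ranksum_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  if (n_a < 1 || n_b < 1) abort("Both groups need at least one observation.")
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n_a)])
  mu <- n_a * (N + 1) / 2
  ties <- table(c(a, b))
  v <- n_a * n_b / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (v > 0) (W - mu) / sqrt(v) else 0
  if (max(n_a, n_b) < exact_cutoff) {
    sums <- utils::combn(r, n_a, sum)
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
  } else {
    p <- if (v > 0) 2 * pnorm(-abs(z)) else 1
  }
  new_stat_result("wilcoxon_ranksum", z, p, N)
}

#' Wilcoxon signed rank test (paired or one-sample)
#'
#' Differences of zero are discarded; the remaining absolute differences
#' are ranked with average ranks for ties. Reports the tie-corrected z
#' statistic and a two-tailed p value, exact by enumeration of all sign
#' assignments when fewer than 9 nonzero differences remain.
#'
#' @param x Numeric vector (differences, or first member of each pair).
#' @param y Optional second member of each pair.
#' @return A one-row tibble: `statistic`, `estimate` (z), `p_value`, `n`
#'   (nonzero differences used).
#' @export
signedrank_test <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    abort("All paired differences are zero; the signed rank test is degenerate.")
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (v > 0) (W - mu) / sqrt(v) else 0
  if (n < exact_cutoff) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- as.numeric(signs %*% r)
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
  } else {
    p <- if (v > 0) 2 * pnorm(-abs(z)) else 1
  }
  new_stat_result("wilcoxon_signedrank", z, p, n)
}

#' Exclude participants by missed observation-lottery trials
#'
#' Removes participants whose count of trials without an
#' observation-lottery choice is strictly greater than the threshold
#' (performance failures), keeping behaviour comparable across the
#' analyzed sample. Excluded ids are reported via a message and attached
#' as the `excluded` attribute.
#'
#' @param participants A tibble of participants.
#' @param missed Per-participant miss counts: a numeric vector or the name
#'   of a column of `participants` (default `"n_missed"`).
#' @param threshold Maximum tolerated misses (default 30; "more than 30"
#'   excludes).
#' @return The filtered tibble.
#' @export
apply_exclusion <- function(participants, missed = "n_missed",
                            threshold = 30) {
  counts <- if (is.character(missed)) {
    if (!missed %in% names(participants)) {
      abort(sprintf("Column '%s' not found in `participants`.", missed))
    }
    participants[[missed]]
  } else {
    missed
  }
  if (length(counts) != nrow(participants)) {
    abort("Need one miss count per participant.")
  }
  if (any(counts < 0, na.rm = TRUE)) {
    abort("Miss counts cannot be negative.")
  }
  drop <- !is.na(counts) & counts > threshold
  ids <- if ("participant" %in% names(participants)) {
    participants$participant[drop]
  } else {
    which(drop)
  }
  inform(sprintf("Excluded %d of %d participants (> %d missed trials)%s.",
                 sum(drop), nrow(participants), threshold,
                 if (sum(drop) > 0) {
                   paste0(": ", paste(ids, collapse = ", "))
                 } else ""))
  out <- participants[!drop, , drop = FALSE]
  attr(out, "excluded") <- ids
  out
}
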