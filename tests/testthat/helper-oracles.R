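# Independent brute-force oracles used to check the package's statistics
# and model arithmetic. These deliberately use the most literal possible
# computation, never the package's own code paths.

# Direct power-weighted summation of the recency-weighted history.
oracle_decayed_sum <- function(values, t, gamma) {
  sum(gamma^(t - seq_len(t)) * values[seq_len(t)])
}

# Pearson correlation from first principles (no cor()).
oracle_pearson <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# Exhaustive permutation distribution of the rank-sum statistic; z is the
# observed statistic standardized by the permutation mean and SD, p the
# two-tailed tail mass.
oracle_ranksum <- function(a, b) {
  r <- rank(c(a, b))
  n_a <- length(a)
  W <- sum(r[seq_len(n_a)])
  sums <- utils::combn(seq_along(r), n_a, function(idx) sum(r[idx]))
  mu <- mean(sums)
  sdev <- sqrt(mean((sums - mu)^2))
  list(
    z = if (sdev > 0) (W - mu) / sdev else 0,
    p = mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
  )
}

# Exhaustive sign-flip distribution of the signed-rank statistic.
oracle_signedrank <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.numeric(signs %*% r)
  mu <- mean(sums)
  sdev <- sqrt(mean((sums - mu)^2))
  list(
    z = if (sdev > 0) (W - mu) / sdev else 0,
    p = mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
  )
}

# A small hand-built two-trial session: a certain gain of +1, then a chosen
# gamble with EV +0.5 whose +1 outcome is revealed (RPE +0.5), probed after
# trial 2. Used wherever a fully known history is needed.
tiny_session <- function() {
  s <- build_risky_session("lab", seed = 1, n_trials = 2, n_probes = 1)
  s$choice <- c("certain", "gamble")
  s$certain_amount <- c(1, 0)
  s$gamble_hi <- c(2, 1)
  s$gamble_lo <- c(0, 0)
  s$gamble_p <- 0.5
  s$outcome <- c(1, 1)
  s$revealed <- TRUE
  s$cr <- c(1, 0)
  s$ev <- c(0, 0.5)
  s$rpe <- c(0, 0.5)
  s
}

# One simulated lab participant with known generating parameters.
simulated_participant <- function(params, noise_sd = 0, seed = 1,
                                  variant = "lab") {
  s <- build_risky_session(variant, seed = seed)
  s <- simulate_choices(s, seed = seed + 1)
  suppressWarnings(
    simulate_ratings(s, params, noise_sd = noise_sd, seed = seed + 2)
  )
}
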