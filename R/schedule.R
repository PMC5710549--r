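#' Build a happiness-probe schedule with gaps of 2 or 3 trials
#'
#' Probes occur "every 2 to 3 trials". Given the total number of trials and
#' probes, the multiset of gaps is fixed: it is the unique non-negative
#' integer solution of `a + b = n_probes`, `2a + 3b = n_trials` (a gaps of 2,
#' b gaps of 3). Only the order of the gaps is random; the first probe falls
#' after the first gap and the last after the final trial.
#'
#' @param n_trials Total number of choice trials.
#' @param n_probes Number of happiness probes.
#' @param seed Optional integer seed controlling the gap order.
#'
#' @return Integer vector of length `n_probes`: the trial indices after which
#'   a probe occurs (strictly increasing, ending at `n_trials`).
#' @examples
#' s <- build_schedule(160, 66, seed = 1)
#' table(diff(c(0, s))) # 38 gaps of 2, 28 gaps of 3
#' @export
build_schedule <- function(n_trials, n_probes, seed = NULL) {
  n_trials <- as.integer(n_trials)
  n_probes <- as.integer(n_probes)
  # a + b = n_probes, 2a + 3b = n_trials  =>  b = n_trials - 2 n_probes
  b <- n_trials - 2L * n_probes
  a <- n_probes - b
  if (a < 0L || b < 0L) {
    abort(sprintf(
      "No {2,3}-gap schedule exists for %d trials and %d probes.",
      n_trials, n_probes
    ))
  }
  gaps <- c(rep(2L, a), rep(3L, b))
  gaps <- with_seed(seed, sample(gaps))
  cumsum(gaps)
}
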