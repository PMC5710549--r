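#' Expected value of a two-outcome gamble
#'
#' The expected value (EV) of a risky option is its probability-weighted
#' average return: `p_hi * outcome_hi + (1 - p_hi) * outcome_lo`. All
#' arguments are vectorized and recycled to a common length.
#'
#' @param outcome_hi Numeric, the better outcome (money units).
#' @param outcome_lo Numeric, the worse outcome; must not exceed `outcome_hi`.
#' @param p_hi Probability of the better outcome, in \[0, 1\].
#'
#' @return Numeric vector of expected values.
#' @examples
#' gamble_ev(1, -1, 0.75) # +0.50
#' gamble_ev(72, 0, 0.5)  # spinner midpoint, 36 points
#' @export
gamble_ev <- function(outcome_hi, outcome_lo, p_hi) {
  n <- max(length(outcome_hi), length(outcome_lo), length(p_hi))
  outcome_hi <- rep_len(outcome_hi, n)
  outcome_lo <- rep_len(outcome_lo, n)
  p_hi <- rep_len(p_hi, n)
  if (any(p_hi < 0 | p_hi > 1, na.rm = TRUE)) {
    abort("`p_hi` must lie in [0, 1].")
  }
  bad <- !is.na(outcome_hi) & !is.na(outcome_lo) & outcome_hi < outcome_lo
  if (any(bad)) {
    abort("`outcome_hi` must be >= `outcome_lo` for every gamble.")
  }
  p_hi * outcome_hi + (1 - p_hi) * outcome_lo
}

#' Reward prediction error for a trial
#'
#' The reward prediction error (RPE) is the difference between the
#' experienced and the predicted reward: `outcome - ev` when the outcome is
#' revealed. When the outcome of a chosen gamble is withheld no prediction
#' error occurs and the RPE is defined as zero.
#'
#' @param outcome Numeric outcome actually received; may be `NA` when
#'   `revealed` is `FALSE`.
#' @param ev Numeric expected value of the chosen gamble.
#' @param revealed Logical; was the outcome shown?
#'
#' @return Numeric vector of RPEs (0 wherever `revealed` is `FALSE`).
#' @examples
#' trial_rpe(1, 0.5, TRUE)    # +0.5
#' trial_rpe(NA, 0.5, FALSE)  # 0: hidden outcome carries no surprise
#' @export
trial_rpe <- function(outcome, ev, revealed) {
  n <- max(length(outcome), length(ev), length(revealed))
  outcome <- rep_len(outcome, n)
  ev <- rep_len(ev, n)
  revealed <- rep_len(revealed, n)
  if (any(revealed & is.na(outcome))) {
    abort("Malformed trial: `outcome` is missing on a revealed trial.")
  }
  ifelse(revealed, outcome - ev, 0)
}
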