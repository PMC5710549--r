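variant_spec <- function(variant) {
  switch(variant,
    lab = list(n_trials = 160L, n_probes = 66L, endowment = NA_real_,
               currency = "GBP"),
    smartphone = list(n_trials = 30L, n_probes = 12L, endowment = 500,
                      currency = "points"),
    probabilistic = list(n_trials = 164L, n_probes = 0L, endowment = NA_real_,
                         currency = "GBP"),
    abort(sprintf("Unknown task variant '%s'.", variant))
  )
}

#' Default stake distributions for the risky decision tasks
#'
#' The published task descriptions do not include the monetary stake
#' distributions, so they are configurable. The defaults give 50/50 gambles
#' whose spread straddles the certain amount, with pound-scale stakes in the
#' laboratory task and point-scale stakes in the smartphone task.
#'
#' @param variant `"lab"` or `"smartphone"`.
#' @return A list with elements `certain_min`, `certain_max` (range of the
#'   certain reward), `spread_min`, `spread_max` (range of the gamble's
#'   half-spread above and below the certain amount) and `p_hi`.
#' @export
stake_defaults <- function(variant = c("lab", "smartphone")) {
  variant <- match.arg(variant)
  if (variant == "lab") {
    list(certain_min = -1, certain_max = 1, spread_min = 0.5, spread_max = 2,
         p_hi = 0.5)
  } else {
    list(certain_min = -50, certain_max = 50, spread_min = 25, spread_max = 100,
         p_hi = 0.5)
  }
}

new_mood_session <- function(trials, variant, endowment = NA_real_) {
  out <- as_tibble(trials)
  attr(out, "variant") <- variant
  attr(out, "endowment") <- endowment
  class(out) <- c("mood_session", class(out))
  out
}

#' @export
print.mood_session <- function(x, ...) {
  v <- session_variant(x)
  cat(sprintf(
    "<mood_session> %s: %d trials, %d probes%s\n", v, nrow(x),
    sum(x$probe),
    if (!is.na(session_endowment(x))) {
      sprintf(", endowment %g", session_endowment(x))
    } else ""
  ))
  NextMethod()
}

#' Session attribute accessors
#'
#' @param session A `mood_session` tibble.
#' @return The task variant string, or the starting endowment (`NA` for
#'   variants without one).
#' @export
session_variant <- function(session) attr(session, "variant")

#' @rdname session_variant
#' @export
session_endowment <- function(session) attr(session, "endowment")

#' Build a risky decision session template
#'
#' Creates the trial-by-trial structure of the laboratory task (160 choice
#' trials, 66 happiness probes, outcomes hidden on half of the gamble
#' choices downstream) or its smartphone variant (30 trials, 12 probes,
#' 500-point endowment, equal-probability spinners resolved immediately).
#' The template carries certain amounts, gamble outcomes and the probe
#' schedule; choices, outcomes and ratings are filled in by
#' [simulate_choices()] and [simulate_ratings()].
#'
#' @param variant `"lab"` or `"smartphone"`.
#' @param seed Optional integer seed (stakes and probe order).
#' @param stakes Stake distribution, see [stake_defaults()].
#' @param n_trials,n_probes Override the variant's trial and probe counts
#'   (a feasible \{2,3\}-gap pair is required).
#'
#' @return A `mood_session` tibble, one row per trial, with columns
#'   `trial`, `choice`, `certain_amount`, `gamble_hi`, `gamble_lo`,
#'   `gamble_p`, `outcome`, `revealed`, `cr`, `ev`, `rpe`, `probe`,
#'   `rating`.
#' @examples
#' s <- build_risky_session("smartphone", seed = 1)
#' nrow(s)        # 30
#' sum(s$probe)   # 12
#' @export
build_risky_session <- function(variant = c("lab", "smartphone"), seed = NULL,
                                stakes = stake_defaults(variant),
                                n_trials = NULL, n_probes = NULL) {
  variant <- match.arg(variant)
  vs <- variant_spec(variant)
  n_trials <- as.integer(n_trials %||% vs$n_trials)
  n_probes <- as.integer(n_probes %||% vs$n_probes)
  probe_at <- build_schedule(n_trials, n_probes, seed = child_seed(seed, 1L))
  trials <- with_seed(child_seed(seed, 2L), {
    certain <- runif(n_trials, stakes$certain_min, stakes$certain_max)
    up <- runif(n_trials, stakes$spread_min, stakes$spread_max)
    down <- runif(n_trials, stakes$spread_min, stakes$spread_max)
    tibble(
      trial = seq_len(n_trials),
      choice = NA_character_,
      certain_amount = certain,
      gamble_hi = certain + up,
      gamble_lo = certain - down,
      gamble_p = stakes$p_hi,
      outcome = NA_real_,
      revealed = NA,
      cr = NA_real_,
      ev = NA_real_,
      rpe = NA_real_,
      probe = seq_len(n_trials) %in% probe_at,
      rating = NA_real_
    )
  })
  new_mood_session(trials, variant, vs$endowment)
}

#' Build a probabilistic reward task session
#'
#' The scanner task presents, on each of 164 trials, an "observation
#' lottery" winning +1 or losing -1 pound with win probability 0%, 25%, 75%
#' or 100% (each level equally often), paired with a statewise-dominated
#' alternative whose two outcomes are both 0.5 pounds worse. A
#' reward-maximizing agent therefore always picks the observation lottery
#' and no learning is required. Outcomes are always revealed.
#'
#' @param seed Optional integer seed (trial order).
#' @param n_trials Number of trials; must be divisible by 4 so the four win
#'   probabilities can be balanced.
#'
#' @return A `mood_session` tibble with the risky-session columns plus
#'   `p_win`, `alt_hi`, `alt_lo` describing the observation lottery and its
#'   dominated alternative. Choices and outcomes are filled by
#'   [simulate_choices()].
#' @examples
#' s <- build_probabilistic_session(seed = 1)
#' table(s$p_win) # 41 trials at each of 0, 0.25, 0.75, 1
#' @export
build_probabilistic_session <- function(seed = NULL, n_trials = 164L) {
  n_trials <- as.integer(n_trials)
  levels <- c(0, 0.25, 0.75, 1)
  if (n_trials %% length(levels) != 0L) {
    abort("`n_trials` must be divisible by 4 to balance the lottery types.")
  }
  p_win <- with_seed(seed, sample(rep(levels, n_trials / length(levels))))
  trials <- tibble(
    trial = seq_len(n_trials),
    choice = NA_character_,
    certain_amount = NA_real_,
    gamble_hi = 1,
    gamble_lo = -1,
    gamble_p = p_win,
    p_win = p_win,
    alt_hi = 0.5,
    alt_lo = -1.5,
    outcome = NA_real_,
    revealed = NA,
    cr = NA_real_,
    ev = NA_real_,
    rpe = NA_real_,
    probe = FALSE,
    rating = NA_real_
  )
  new_mood_session(trials, "probabilistic", NA_real_)
}

#' Validate the structural invariants of a session
#'
#' Checks the printed trial/probe counts for the variant, the \{2,3\} probe
#' gap rule, mutual exclusivity of the certain-reward and expected-value
#' terms, the zero-RPE-when-unrevealed rule, and the \[0,1\] rating range.
#'
#' @param session A `mood_session` tibble.
#' @param strict If `TRUE` (default) the variant's canonical trial and probe
#'   counts are enforced; set `FALSE` for custom-length sessions.
#' @return `session`, invisibly; errors describe the first violated rule.
#' @export
validate_session <- function(session, strict = TRUE) {
  v <- session_variant(session)
  vs <- variant_spec(v)
  if (strict && nrow(session) != vs$n_trials) {
    abort(sprintf("A %s session must have %d trials, found %d.",
                  v, vs$n_trials, nrow(session)))
  }
  probes <- which(session$probe)
  if (strict && length(probes) != vs$n_probes) {
    abort(sprintf("A %s session must have %d probes, found %d.",
                  v, vs$n_probes, length(probes)))
  }
  gaps <- diff(c(0L, probes))
  if (length(probes) > 0 && !all(gaps %in% c(2L, 3L))) {
    abort(sprintf(
      "Probe gaps must all be 2 or 3 trials; found gap(s) of %s.",
      paste(sort(unique(gaps[!gaps %in% c(2L, 3L)])), collapse = ", ")
    ))
  }
  decided <- !is.na(session$choice)
  both <- decided & session$cr != 0 & session$ev != 0
  if (any(both, na.rm = TRUE)) {
    abort(sprintf(
      "Trial(s) %s carry both a certain-reward and an expected-value term; terms for unchosen options must be zero.",
      paste(which(both), collapse = ", ")
    ))
  }
  hidden_rpe <- decided & !is.na(session$revealed) & !session$revealed &
    session$rpe != 0
  if (any(hidden_rpe, na.rm = TRUE)) {
    abort(sprintf(
      "Trial(s) %s have an unrevealed outcome but a nonzero RPE; the RPE must be zero when the outcome is not revealed.",
      paste(which(hidden_rpe), collapse = ", ")
    ))
  }
  ratings <- session$rating[session$probe]
  if (any(!is.na(ratings) & (ratings < 0 | ratings > 1))) {
    abort("Happiness ratings must lie in [0, 1].")
  }
  invisible(session)
}

#' Per-trial neuroimaging regressor values for a probabilistic session
#'
#' Returns the two parametric-modulator series used for reward-related
#' analyses: the chosen lottery's expected value at the choice period and
#' the reward prediction error at the outcome period. Trials where the
#' dominated alternative was chosen (performance errors) yield `NA` in both
#' series.
#'
#' @param session A simulated probabilistic `mood_session` (choices filled).
#' @return A tibble with columns `trial`, `ev`, `rpe`.
#' @export
regressor_series <- function(session) {
  if (session_variant(session) != "probabilistic") {
    abort("Regressor series are defined for probabilistic sessions only.")
  }
  if (anyNA(session$choice)) {
    abort("Simulate choices before extracting regressors.")
  }
  ok <- session$choice == "observation"
  tibble(
    trial = session$trial,
    ev = ifelse(ok, session$ev, NA_real_),
    rpe = ifelse(ok, session$rpe, NA_real_)
  )
}
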