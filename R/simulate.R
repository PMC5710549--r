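#' Default choice-model parameters
#'
#' Choices in the risky tasks are generated from a logistic function of the
#' value difference between the gamble and the certain option:
#' `P(gamble) = plogis(bias + beta * (EV_gamble - CR))`. `beta` is an
#' inverse temperature in 1/money units (so the smartphone default is
#' scaled to its point-valued stakes) and `bias` a risk-taking bias in log
#' odds. The probabilistic task instead uses a fixed per-trial probability
#' `accuracy` of choosing the observation lottery, matching the near-97%
#' correct-choice rates the task is designed to produce.
#'
#' @param variant Task variant id.
#' @return A list with `beta`, `bias` and `accuracy`.
#' @export
choice_defaults <- function(variant = c("lab", "smartphone", "probabilistic")) {
  variant <- match.arg(variant)
  switch(variant,
    lab = list(beta = 2, bias = 0, accuracy = NA_real_),
    smartphone = list(beta = 0.04, bias = 0, accuracy = NA_real_),
    probabilistic = list(beta = NA_real_, bias = NA_real_, accuracy = 0.97)
  )
}

#' Simulate choices and outcomes for a session template
#'
#' Fills the `choice`, `outcome`, `revealed`, `cr`, `ev` and `rpe` columns
#' of a session built by [build_risky_session()] or
#' [build_probabilistic_session()]. In the laboratory variant outcomes are
#' withheld ("outcome added to total") on exactly half of the chosen
#' gambles (a seeded selection; `floor(n/2)` when the count is odd); the
#' smartphone and probabilistic variants always reveal. Terms for unchosen
#' options are zero and the RPE is zero whenever the outcome is not
#' revealed.
#'
#' @param session A `mood_session` template.
#' @param choice Choice-model parameters, see [choice_defaults()]. An
#'   infinite `beta` gives the deterministic value-maximizing agent.
#' @param seed Optional integer seed.
#' @return The session with choice-dependent columns filled.
#' @export
simulate_choices <- function(session, choice = choice_defaults(session_variant(session)),
                             seed = NULL) {
  variant <- session_variant(session)
  if (variant == "probabilistic") {
    return(simulate_probabilistic(session, choice$accuracy, seed))
  }
  n <- nrow(session)
  ev_g <- gamble_ev(session$gamble_hi, session$gamble_lo, session$gamble_p)
  dv <- ev_g - session$certain_amount
  p_gamble <- if (is.infinite(choice$beta)) {
    ifelse(dv > 0, 1, ifelse(dv < 0, 0, 0.5))
  } else {
    stats::plogis(choice$bias + choice$beta * dv)
  }
  with_seed(seed, {
    gamble <- runif(n) < p_gamble
    win <- runif(n) < session$gamble_p
    out <- session
    out$choice <- ifelse(gamble, "gamble", "certain")
    out$outcome <- ifelse(gamble,
                          ifelse(win, session$gamble_hi, session$gamble_lo),
                          session$certain_amount)
    out$revealed <- TRUE
    if (variant == "lab") {
      idx <- which(gamble)
      hidden <- sample(idx, floor(length(idx) / 2))
      out$revealed[hidden] <- FALSE
    }
    out$cr <- ifelse(gamble, 0, session$certain_amount)
    out$ev <- ifelse(gamble, ev_g, 0)
    out$rpe <- ifelse(gamble & out$revealed, out$outcome - out$ev, 0)
    out
  })
}

simulate_probabilistic <- function(session, accuracy, seed) {
  if (is.na(accuracy) || accuracy < 0 || accuracy > 1) {
    abort("`accuracy` must be a probability for the probabilistic task.")
  }
  n <- nrow(session)
  with_seed(seed, {
    correct <- runif(n) < accuracy
    win <- runif(n) < session$p_win
    out <- session
    out$choice <- ifelse(correct, "observation", "other")
    hi <- ifelse(correct, session$gamble_hi, session$alt_hi)
    lo <- ifelse(correct, session$gamble_lo, session$alt_lo)
    out$outcome <- ifelse(win, hi, lo)
    out$revealed <- TRUE
    out$cr <- 0
    out$ev <- gamble_ev(hi, lo, session$p_win)
    out$rpe <- out$outcome - out$ev
    out
  })
}

#' Simulate happiness ratings from the momentary-mood model
#'
#' Generates ratings at the session's probes as the model predictions plus
#' i.i.d. Gaussian noise, clipped to the \[0, 1\] rating scale. The
#' fraction of clipped ratings is attached as the `clip_fraction` attribute
#' and a warning is raised whenever it is nonzero, so simulations can be
#' kept in the regime where clipping is negligible.
#'
#' @param session A simulated `mood_session` (choices filled).
#' @param params Generating [mood_params()].
#' @param noise_sd Rating noise standard deviation (rating units).
#' @param seed Optional integer seed.
#' @param spec Model family generating the ratings.
#' @return The session with the `rating` column filled at probes.
#' @export
simulate_ratings <- function(session, params, noise_sd = 0.05, seed = NULL,
                             spec = "full") {
  pred <- predict_happiness(session, params, spec = spec)
  noisy <- with_seed(seed, pred$prediction + rnorm(nrow(pred), 0, noise_sd))
  clipped <- pmin(1, pmax(0, noisy))
  frac <- mean(clipped != noisy)
  if (frac > 0) {
    warn(sprintf("%.1f%% of simulated ratings were clipped to [0, 1].",
                 100 * frac))
  }
  out <- session
  out$rating[out$probe] <- clipped
  attr(out, "clip_fraction") <- frac
  out
}
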