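#' Momentary-mood model parameters
#'
#' The model predicts the happiness rating at a probe after trial t as
#' \deqn{\hat h(t) = w_0 + \sum_k w_k \sum_{j \le t} \gamma^{t-j} x_{k,j}}
#' where the per-trial series \eqn{x_k} are the certain rewards of chosen
#' safe options (CR), the expected values of chosen gambles (EV) and the
#' reward prediction errors of revealed gamble outcomes (RPE), and
#' \eqn{0 \le \gamma \le 1} is a forgetting factor that makes recent events
#' more influential with an exponential decay. The split-RPE family
#' replaces the RPE weight with separate weights on the RPE's two
#' components, the received reward R and the negated expectation -EV (so
#' `w_r = w_negev = w_rpe` reproduces the full model exactly).
#'
#' @param w0 Baseline mood (rating units; the model's intercept).
#' @param w_cr,w_ev,w_rpe Weights on the decayed CR, EV and RPE histories
#'   (rating units per money unit).
#' @param gamma Forgetting factor in \[0, 1\].
#' @param w_r,w_negev Split-RPE weights on reward and negated expectation
#'   (used by the `split_rpe` family only).
#'
#' @return A `mood_params` list.
#' @examples
#' mood_params(w0 = 0.5, w_cr = 0.1, w_ev = 0.1, w_rpe = 0.1, gamma = 0.5)
#' @export
mood_params <- function(w0 = 0.5, w_cr = 0, w_ev = 0, w_rpe = 0, gamma = 0.5,
                        w_r = NULL, w_negev = NULL) {
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    abort("`gamma` must be a single number in [0, 1].")
  }
  structure(
    list(w0 = w0, w_cr = w_cr, w_ev = w_ev, w_rpe = w_rpe, gamma = gamma,
         w_r = w_r, w_negev = w_negev),
    class = "mood_params"
  )
}

#' @export
print.mood_params <- function(x, ...) {
  cat("<mood_params>\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  cat(paste(sprintf("  %-8s %g", names(flat), unlist(flat)), collapse = "\n"),
      "\n")
  invisible(x)
}

# Term definitions per model family. Each term names the per-trial series
# (built by term_series) and the mood_params element holding its weight.
model_families <- list(
  full = c(cr = "w_cr", ev = "w_ev", rpe = "w_rpe"),
  no_expectation = c(cr = "w_cr", rpe = "w_rpe"),
  split_rpe = c(cr = "w_cr", ev = "w_ev", r = "w_r", negev = "w_negev")
)

#' Model families available for fitting and comparison
#'
#' `"full"` uses CR, EV and RPE terms; `"no_expectation"` omits the EV
#' term; `"split_rpe"` splits the RPE into its reward and negated
#' expectation components (on revealed gamble trials only, mirroring the
#' zero-RPE-when-unrevealed rule).
#'
#' @return Character vector of family ids.
#' @export
model_specs <- function() names(model_families)

#' Number of free parameters of a model family
#'
#' The intercept `w0`, one weight per term, and the forgetting factor.
#'
#' @param spec A model family id, see [model_specs()].
#' @return Integer count (full: 5, no_expectation: 4, split_rpe: 6).
#' @export
n_params <- function(spec) {
  terms <- model_terms(spec)
  length(terms) + 2L
}

model_terms <- function(spec) {
  if (!spec %in% names(model_families)) {
    abort(sprintf("Unknown model family '%s' (use one of %s).", spec,
                  paste(model_specs(), collapse = ", ")))
  }
  model_families[[spec]]
}

# Per-trial value series feeding the decayed sums. Gamble trials with
# hidden outcomes keep their EV term (the expectation was formed) but
# contribute zero to the RPE, R and -EV(revealed) series.
term_series <- function(session, terms) {
  revealed_gamble <- !is.na(session$revealed) & session$revealed &
    session$choice %in% c("gamble", "observation", "other")
  series <- lapply(names(terms), function(term) {
    switch(term,
      cr = session$cr,
      ev = session$ev,
      rpe = session$rpe,
      r = ifelse(revealed_gamble, session$outcome, 0),
      negev = ifelse(revealed_gamble, -session$ev, 0),
      abort(sprintf("Unknown model term '%s'.", term))
    )
  })
  names(series) <- names(terms)
  series
}

#' Recency-weighted sum of a per-trial series
#'
#' Computes \eqn{\sum_{j=1}^{t} \gamma^{t-j} v_j}: with `gamma = 0` only
#' the current trial counts, with `gamma = 1` the plain running sum.
#'
#' @param values Numeric per-trial series (trial 1 first).
#' @param t Trial index (or vector of indices) at which to evaluate.
#' @param gamma Forgetting factor in \[0, 1\].
#' @return Numeric vector, one decayed sum per element of `t`.
#' @examples
#' decayed_sum(c(5, 3, 7), 3, gamma = 0) # 7
#' decayed_sum(c(5, 3, 7), 3, gamma = 1) # 15
#' @export
decayed_sum <- function(values, t, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    abort("`gamma` must be a single number in [0, 1].")
  }
  t <- as.integer(t)
  if (any(t < 1L | t > length(values))) {
    abort("`t` must index into `values`.")
  }
  # s_t = gamma * s_{t-1} + v_t, a first-order recursive filter
  s <- as.numeric(stats::filter(values, gamma, method = "recursive"))
  s[t]
}

# Decayed design matrix at the probe trials: one column per model term.
mood_design <- function(series, probe_at, gamma) {
  X <- vapply(series, decayed_sum, numeric(length(probe_at)),
              t = probe_at, gamma = gamma)
  matrix(X, nrow = length(probe_at), dimnames = list(NULL, names(series)))
}

#' Predict happiness ratings at a session's probes
#'
#' Applies the momentary-mood equation: the prediction at each probe is the
#' baseline plus the weighted, recency-discounted sums of the per-trial CR,
#' EV and RPE series up to and including the probed trial (terms for
#' unchosen options and unrevealed outcomes are zero). Later trials cannot
#' influence earlier probes.
#'
#' @param session A simulated `mood_session` (choices and outcomes filled).
#' @param params A [mood_params()] object; the family's weights must be
#'   present (`w_r`/`w_negev` for `split_rpe`).
#' @param spec Model family id, see [model_specs()].
#'
#' @return A tibble with columns `trial` (probe trial index) and
#'   `prediction` (model-predicted rating, unclipped).
#' @export
predict_happiness <- function(session, params, spec = "full") {
  terms <- model_terms(spec)
  weights <- lapply(params[terms], identity)
  missing <- vapply(weights, is.null, logical(1))
  if (any(missing)) {
    abort(sprintf(
      "Model family '%s' needs parameter(s) %s, absent from `params`.",
      spec, paste(terms[missing], collapse = ", ")
    ))
  }
  probe_at <- which(session$probe)
  X <- mood_design(term_series(session, terms), probe_at, params$gamma)
  tibble(
    trial = probe_at,
    prediction = as.numeric(params$w0 + X %*% unlist(weights))
  )
}
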