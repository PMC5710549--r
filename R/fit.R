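#' Fit the momentary-mood model to one participant's ratings
#'
#' Given the forgetting factor, the model is linear in its weights, so the
#' global least-squares solution is found by an exhaustive search: for each
#' `gamma` on a fixed grid the decayed design matrix is built and the
#' weights are solved in closed form by ordinary least squares; the
#' `(gamma, weights)` pair with the smallest residual sum of squares wins,
#' with exact ties broken toward the smaller `gamma`. No bounds are placed
#' on the weights.
#'
#' Degenerate ratings with zero variance yield the convention
#' `w0 = mean(rating)`, all weights 0 and `r2 = 0`, flagged in the result.
#'
#' @param session A simulated `mood_session` carrying ratings at its probes
#'   (or supply `ratings` directly).
#' @param spec Model family id, see [model_specs()].
#' @param gamma_grid Candidate forgetting factors (default: step 0.01 over
#'   \[0, 1\]).
#' @param ratings Optional rating series overriding the session's probe
#'   ratings; length must equal the number of probes.
#'
#' @return A `mood_fit` object: fitted [mood_params()], coefficient vector,
#'   `r2`, `sse`, `n_probes`, `k_params`, the BIC-style information
#'   criterion `ic` and the family id. [tidy()] and [glance()] methods
#'   return tibbles.
#' @seealso [information_criterion()], [compare_models()]
#' @export
fit_mood_model <- function(session, spec = "full",
                           gamma_grid = seq(0, 1, by = 0.01),
                           ratings = NULL) {
  terms <- model_terms(spec)
  probe_at <- which(session$probe)
  if (is.null(ratings)) {
    ratings <- session$rating[probe_at]
  } else if (length(ratings) != length(probe_at)) {
    abort("`ratings` must supply one value per probe.")
  }
  keep <- !is.na(ratings)
  ratings <- ratings[keep]
  probe_at <- probe_at[keep]
  n <- length(ratings)
  k <- n_params(spec)
  if (n < k) {
    abort(sprintf(
      "Underdetermined fit: %d rated probes for %d free parameters ('%s').",
      n, k, spec
    ))
  }
  if (any(gamma_grid < 0 | gamma_grid > 1)) {
    abort("`gamma_grid` must lie within [0, 1].")
  }
  gamma_grid <- sort(gamma_grid)

  tss <- sum((ratings - mean(ratings))^2)
  if (tss == 0) {
    warn("Ratings have zero variance; returning the degenerate fit w0 = mean rating.")
    coefs <- c(w0 = mean(ratings), setNames(rep(0, length(terms)), terms))
    fitted <- tibble(trial = probe_at, rating = ratings,
                     fitted = rep(mean(ratings), n))
    return(new_mood_fit(coefs, terms, gamma = gamma_grid[1], spec = spec,
                        sse = 0, r2 = 0, n = n, k = k, zero_variance = TRUE,
                        fitted = fitted))
  }

  series <- term_series(session, terms)
  best <- list(sse = Inf, gamma = NA_real_, coef = NULL, fitted = NULL)
  for (g in gamma_grid) {
    X <- cbind(1, mood_design(series, probe_at, g))
    fit <- stats::.lm.fit(X, ratings)
    sse <- sum(fit$residuals^2)
    if (sse < best$sse) {
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0 # aliased term (e.g. an all-zero regressor)
      best <- list(sse = sse, gamma = g, coef = cf,
                   fitted = ratings - fit$residuals)
    }
  }
  coefs <- setNames(best$coef, c("w0", names(terms)))
  new_mood_fit(coefs, terms, gamma = best$gamma, spec = spec,
               sse = best$sse, r2 = 1 - best$sse / tss, n = n, k = k,
               zero_variance = FALSE,
               fitted = tibble(trial = probe_at, rating = ratings,
                               fitted = best$fitted))
}

new_mood_fit <- function(coefs, terms, gamma, spec, sse, r2, n, k,
                         zero_variance, fitted = NULL) {
  args <- setNames(as.list(coefs[names(terms)]), unname(terms))
  params <- do.call(mood_params, c(list(w0 = coefs[["w0"]], gamma = gamma),
                                   args))
  structure(
    list(params = params, coefficients = coefs, gamma = gamma, spec = spec,
         sse = sse, r2 = r2, n_probes = n, k_params = k,
         ic = information_criterion(sse, n, k),
         zero_variance = zero_variance, fitted = fitted),
    class = "mood_fit"
  )
}

#' @export
print.mood_fit <- function(x, ...) {
  cat(sprintf("<mood_fit> family '%s': r2 = %.3f, gamma = %.2f, BIC = %.1f (n = %d probes)\n",
              x$spec, x$r2, x$gamma, x$ic, x$n_probes))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_mood_model
#' @param x,object A `mood_fit`.
#' @param ... Unused.
#' @method tidy mood_fit
#' @export
tidy.mood_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = as.numeric(x$coefficients))
}

#' @rdname fit_mood_model
#' @method glance mood_fit
#' @export
glance.mood_fit <- function(x, ...) {
  tibble(spec = x$spec, r2 = x$r2, sse = x$sse, gamma = x$gamma,
         n_probes = x$n_probes, k_params = x$k_params, ic = x$ic,
         zero_variance = x$zero_variance)
}

#' BIC-style information criterion for a least-squares mood fit
#'
#' A Gaussian-likelihood Bayesian information criterion computed from the
#' residual sum of squares: `n * log(max(sse, eps) / n) + k * log(n)`.
#' Smaller is better. This is a standard desk-scale surrogate for model
#' evidence in a fixed-effects (summed across participants) comparison; the
#' floor `eps` keeps perfect fits finite. The residual variance is not
#' counted as a free parameter (it is common to all families and cannot
#' change a ranking).
#'
#' @param sse Residual sum of squares (rating-squared units).
#' @param n_probes Number of rated probes entering the fit.
#' @param k_params Number of free parameters of the family.
#' @param eps Floor on `sse` (default 1e-12).
#' @return The criterion value (a single number).
#' @examples
#' information_criterion(0.165, 66, 5) < information_criterion(0.25, 66, 4)
#' @export
information_criterion <- function(sse, n_probes, k_params, eps = 1e-12) {
  if (n_probes <= 0) abort("`n_probes` must be positive.")
  if (sse < 0) abort("`sse` must be non-negative.")
  n_probes * log(max(sse, eps) / n_probes) + k_params * log(n_probes)
}
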