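#' Compare model families across a cohort of fits
#'
#' A fixed-effects model comparison: the information criterion is summed
#' per family across participants and the family with the smallest total
#' wins. Per-participant winner counts are reported alongside. Ties — in
#' the summed criterion or within a participant — are reported, never
#' silently broken.
#'
#' @param fit_table A tidy fit table with one row per participant and
#'   family, carrying at least columns `participant`, `spec` and `ic`
#'   (as produced by [fit_cohort()]).
#' @return A `mood_model_comparison` object with a `summary` tibble
#'   (`spec`, `total_ic`, `n_best`), the winning family id(s) in `winner`,
#'   and a `tie` flag. [tidy()] returns the summary tibble.
#' @export
compare_models <- function(fit_table) {
  needed <- c("participant", "spec", "ic")
  if (!all(needed %in% names(fit_table))) {
    abort("`fit_table` must have columns participant, spec and ic.")
  }
  specs <- unique(fit_table$spec)
  grid <- tidyr::expand_grid(participant = unique(fit_table$participant),
                             spec = specs)
  missing <- dplyr::anti_join(grid, fit_table, by = c("participant", "spec"))
  if (nrow(missing) > 0) {
    abort(sprintf(
      "Every participant must be fitted under every family; missing: %s.",
      paste(sprintf("%s x %s", missing$participant, missing$spec),
            collapse = "; ")
    ))
  }

  per_part <- fit_table |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(is_best = .data$ic == min(.data$ic)) |>
    dplyr::ungroup()
  summary <- per_part |>
    dplyr::group_by(.data$spec) |>
    dplyr::summarise(total_ic = sum(.data$ic), n_best = sum(.data$is_best),
                     .groups = "drop") |>
    dplyr::arrange(.data$total_ic)
  winner <- summary$spec[summary$total_ic == min(summary$total_ic)]
  structure(
    list(summary = summary, winner = winner, tie = length(winner) > 1L,
         n_participants = dplyr::n_distinct(fit_table$participant)),
    class = "mood_model_comparison"
  )
}

#' @export
print.mood_model_comparison <- function(x, ...) {
  cat(sprintf(
    "<mood_model_comparison> %d participants, BIC approximation to model evidence (fixed effects)\n",
    x$n_participants
  ))
  print(x$summary)
  if (x$tie) {
    cat("Tied winners:", paste(x$winner, collapse = ", "), "\n")
  } else {
    cat("Winner:", x$winner, "\n")
  }
  invisible(x)
}

#' @rdname compare_models
#' @param x A `mood_model_comparison`.
#' @param ... Unused.
#' @method tidy mood_model_comparison
#' @export
tidy.mood_model_comparison <- function(x, ...) x$summary
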