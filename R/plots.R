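#' Plot observed and model-predicted happiness over a session
#'
#' @param object A `mood_fit`.
#' @param ... Unused.
#' @return A ggplot: ratings and fitted values against probe trial index.
#' @method autoplot mood_fit
#' @export
autoplot.mood_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$fitted, c("rating", "fitted"),
                           names_to = "series", values_to = "happiness")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$happiness,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(rating = "grey40",
                                            fitted = "#d95f02")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "trial", y = "happiness",
      title = sprintf("Momentary mood fit ('%s'): r2 = %.2f, gamma = %.2f",
                      object$spec, object$r2, object$gamma)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' @param object A `mood_model_comparison`.
#' @param ... Unused.
#' @return A ggplot of summed information criterion differences from the
#'   winning family (smaller is better, winner at zero).
#' @method autoplot mood_model_comparison
#' @export
autoplot.mood_model_comparison <- function(object, ...) {
  d <- dplyr::mutate(object$summary,
                     delta = .data$total_ic - min(.data$total_ic))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$spec, .data$delta),
                                  y = .data$delta)) +
    ggplot2::geom_col(fill = "#1b9e77") +
    ggplot2::labs(x = NULL, y = "summed IC difference from winner",
                  title = "Model comparison (BIC approximation)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a fitted parameter against symptom severity
#'
#' @param cohort A `mood_cohort`.
#' @param fits Its fit table (the `full` family rows are used).
#' @param parameter Fitted parameter to plot (default the baseline mood
#'   parameter `w0`).
#' @return A ggplot with a linear trend overlay.
#' @export
plot_linkage <- function(cohort, fits, parameter = "w0") {
  full <- dplyr::filter(fits, .data$spec == "full")
  d <- dplyr::inner_join(
    tibble(participant = cohort$participant, symptom = cohort$symptom,
           group = cohort$group),
    dplyr::select(full, dplyr::all_of(c("participant", parameter))),
    by = "participant"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$symptom, y = .data[[parameter]],
                                  colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, colour = "black",
                         se = FALSE, linewidth = 0.5) +
    ggplot2::labs(x = "symptom severity", y = sprintf("fitted %s", parameter),
                  title = "Fitted parameter vs symptom severity") +
    ggplot2::theme_minimal()
}
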