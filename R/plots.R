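#' Plot the PPV distributions of a simulation study
#'
#' Density of the per-replicate positive predictive values, one panel per
#' selection fraction, one curve per score — the standard display for
#' comparing the stability of score-based selection rules.
#'
#' @param object A `study_summary` from [run_simulation_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot study_summary
#' @export
autoplot.study_summary <- function(object, ...) {
  df <- object$ppv |>
    dplyr::mutate(panel = sprintf("top %g%% selection", 100 * .data$fraction))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ppv, colour = .data$score)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "positive predictive value", y = "density",
                  colour = "score") +
    ggplot2::theme_minimal()
}

#' Compare two family scores (shrinkage plot)
#'
#' Scatter of one score against another for the same families, coloured by
#' family size. With `x` the empirical proportion (LRC) and `y` its
#' model-based version (mLRC), the plot shows the shrinkage pattern: small
#' families pulled down at high LRC and up at LRC 0.
#'
#' @param x,y Score tibbles for the same families.
#' @return A ggplot object.
#' @export
plot_score_comparison <- function(x, y) {
  df <- dplyr::inner_join(
    dplyr::select(x, "family_id", "size", x_value = "value"),
    dplyr::select(y, "family_id", y_value = "value"),
    by = "family_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_value, y = .data$y_value,
                                   colour = factor(.data$size))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = x$score[1], y = y$score[1], colour = "family size") +
    ggplot2::theme_minimal()
}
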