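# ggplot2 views of profiles and comparisons.

BAND_COLORS <- c(reduced = "#9ecae1", unchanged = "#08519c",
                 elevated = "#cb181d")

#' Plot a library profile
#'
#' Sense versus antisense RPM per transposon on log10 axes; the diagonal
#' marks equal strand abundance, so the cloud sitting above it visualises
#' the antisense bias.
#'
#' @param object A `library_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot library_profile
#' @export
autoplot.library_profile <- function(object, ...) {
  d <- object$transposons
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sense_rpm + 0.5,
                                  y = .data$antisense_rpm + 0.5)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      title = sprintf("%s: transposon piRNA abundance by strand",
                      object$library_id),
      subtitle = sprintf("1U bias %.1f%%, antisense bias %.2f",
                         object$one_u_bias, object$antisense_bias),
      x = "sense RPM (+0.5)", y = "antisense RPM (+0.5)"
    ) +
    ggplot2::theme_minimal()
}

#' Relative-expression heat map
#'
#' Transposon-by-library tile map coloured by band: light blue for reduced
#' (RE < lower bound), blue for unchanged, red for elevated.
#'
#' @param comparison Tibble from [compare_profiles()].
#' @param strand_class Which strand class to show (default `"total"`).
#' @return A ggplot object.
#' @export
plot_re_heatmap <- function(comparison, strand_class = "total") {
  d <- dplyr::filter(comparison, .data$strand_class == !!strand_class)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$library_id,
                                  y = .data$transposon_id,
                                  fill = .data$band)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = BAND_COLORS, na.value = "grey80",
                               drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "RE band",
                  title = sprintf("Relative expression (%s piRNAs)",
                                  strand_class)) +
    ggplot2::theme_minimal()
}

#' Replicate-summary bar plot
#'
#' Mean relative expression per transposon with +/- one sample-SD error
#' bars, the usual presentation of replicate RE summaries.
#'
#' @param summary Tibble from [summarize_comparison()].
#' @param strand_class Which strand class to show (default `"total"`).
#' @return A ggplot object.
#' @export
plot_re_summary <- function(summary, strand_class = "total") {
  d <- dplyr::filter(summary, .data$strand_class == !!strand_class)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$transposon_id,
                                  y = .data$mean_re)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_re - .data$sd_re,
                   ymax = .data$mean_re + .data$sd_re),
      width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "relative expression (baseline = 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
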