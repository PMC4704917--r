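#' Bland-Altman plot
#'
#' Pair differences against pair means with the bias line and limits of
#' agreement; points outside the limits are highlighted. Requires
#' `ggplot2`.
#'
#' @param ba A [bland_altman()] result.
#' @param xlab,ylab Axis labels.
#' @return A `ggplot` object.
#' @export
ba_plot <- function(ba, xlab = "Mean of methods (kJ/day)",
                    ylab = "Difference (kJ/day)") {
  stopifnot(inherits(ba, "bland_altman"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ba_plot() needs the 'ggplot2' package.",
          class = "dietsense_argument_error")
  }
  ggplot2::ggplot(ba$pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outside),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red3")) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}
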