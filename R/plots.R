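#' Histogram of per-cell output with a distinct zero bar
#'
#' @param summary A [classify_states()] result.
#' @param title Plot title.
#' @return A ggplot object (requires the \pkg{ggplot2} package).
#' @export
plot_state_histogram <- function(summary, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  stopifnot(inherits(summary, "subpop_summary"))
  h <- summary$histogram
  mids <- (h$breaks[-1] + h$breaks[-length(h$breaks)]) / 2
  df <- data.frame(mid = mids, count = h$counts,
                   state = ifelse(mids < summary$bin_width / 2,
                                  "zero", "positive"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count,
                                   fill = .data$state)) +
    ggplot2::geom_col(width = summary$bin_width * 0.9) +
    ggplot2::scale_fill_manual(values = c(zero = "black",
                                          positive = "magenta3")) +
    ggplot2::labs(x = "per-cell output (molecules)", y = "cells",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Dose-response plot of the positive-state fraction
#'
#' @param curve A [dose_response()] result.
#' @return A ggplot object (requires the \pkg{ggplot2} package).
#' @export
plot_dose_response <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  stopifnot(inherits(curve, "dose_response"))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$level,
                                      y = .data$positive_fraction)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$positive_fraction -
                    1.96 * .data$positive_fraction_se),
      ymax = pmin(1, .data$positive_fraction +
                    1.96 * .data$positive_fraction_se)),
      alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative input level",
                  y = "positive-state fraction") +
    ggplot2::theme_minimal()
}
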