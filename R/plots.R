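#' Heat map of per-fraction range-error histograms
#'
#' Renders a course's range-error distributions as a heat map: treatment
#' fraction on the x axis, WEPL change (mm) on the y axis, shading
#' proportional to the percent of CTV pixel volume in each bin, with the
#' zero line drawn so drifts of the mean are visible. The display range
#' may be truncated for legibility; the underlying statistics always use
#' the full data.
#'
#' @param histograms Long-format histogram data frame from [run_course()]
#'   (columns `patient`, `fraction`, `angle`, `bin_low`, `bin_high`,
#'   `percent_volume`).
#' @param patient,angle Optional filters.
#' @param ylim Display range in mm, e.g. `c(-15, 15)`; `NULL` shows all.
#' @return A ggplot object.
#' @export
plot_range_heatmap <- function(histograms, patient = NULL, angle = NULL,
                               ylim = c(-15, 15)) {
  df <- histograms
  if (!is.null(patient)) df <- df[df$patient == patient, , drop = FALSE]
  if (!is.null(angle)) df <- df[df$angle == angle, , drop = FALSE]
  if (!nrow(df)) stop("no histogram rows match the requested patient/angle")
  df$mid <- (df$bin_low + df$bin_high) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$mid,
                                        fill = .data$percent_volume)) +
    ggplot2::geom_tile(height = df$bin_high - df$bin_low, width = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "black") +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10",
                                 name = "% volume") +
    ggplot2::labs(x = "Fraction", y = expression(Delta*WEPL~(mm))) +
    ggplot2::theme_minimal()
  if (!is.null(ylim)) p <- p + ggplot2::coord_cartesian(ylim = ylim)
  p
}

#' Per-fraction standard deviation by beam angle
#'
#' Plots the within-fraction standard deviation of the range error against
#' fraction number, one point shape per beam angle — the view that exposes
#' beam-angle dependence of the random error.
#'
#' @param summaries Summary data frame from [run_course()].
#' @return A ggplot object.
#' @export
plot_fraction_sd <- function(summaries) {
  df <- summaries[!is.na(summaries$sd_mm), , drop = FALSE]
  if (!nrow(df)) stop("no summaries with a defined standard deviation")
  df$angle <- factor(df$angle)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$sd_mm,
                                   shape = .data$angle)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Fraction", y = "SD of range error (mm)",
                  shape = "Gantry angle") +
    ggplot2::theme_minimal()
}
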