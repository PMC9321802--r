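# Figures of the risk report.
#
# All probabilities in the report come from the exact discrete distribution;
# the density plots are a kernel-smoothed view of it (Gaussian kernel,
# Silverman's rule-of-thumb bandwidth on the support) for visual comparison
# with the subject's risk, never the basis of any reported number.

#' Density plot of a risk distribution
#'
#' Kernel-smoothed view of the discrete distribution, with the low-risk zone
#' (risk at or below the low boundary) shaded green, the high-risk zone (at
#' or above the high boundary) shaded red, and an optional red vertical line
#' at the subject's risk.
#'
#' @param dist a `risk_distribution`.
#' @param risk optional subject risk to mark.
#' @param zones a `ware_zones` configuration.
#' @return a ggplot object.
#' @export
plot_risk_density <- function(dist, risk = NULL, zones = zone_config()) {
  stopifnot(inherits(dist, "risk_distribution"))
  if (nrow(dist) > 1) {
    den <- stats::density(dist$risk, weights = dist$weight,
                          bw = stats::bw.nrd0(dist$risk),
                          from = 0, to = max(dist$risk, risk, 0) * 1.05 + 0.2)
    curve <- data.frame(x = den$x, y = den$y)
  } else {
    # degenerate point mass: draw a narrow spike
    curve <- data.frame(x = dist$risk + c(-0.01, 0, 0.01), y = c(0, 1, 0))
  }
  xmax <- max(curve$x)
  kind <- attr(dist, "kind")
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = zones$low_boundary,
                      ymin = -Inf, ymax = Inf,
                      fill = "darkgreen", alpha = 0.15) +
    ggplot2::annotate("rect", xmin = zones$high_boundary, xmax = Inf,
                      ymin = -Inf, ymax = Inf,
                      fill = "red", alpha = 0.15) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, xmax)) +
    ggplot2::labs(
      x = "risk (odds ratio relative to the population average)",
      y = "density",
      title = if (kind == "case") "Risk distribution, AMD cases"
              else "Risk distribution, general population") +
    ggplot2::theme_minimal()
  if (!is.null(risk))
    p <- p + ggplot2::geom_vline(xintercept = risk, colour = "red",
                                 linewidth = 0.9)
  p
}

#' Pie chart of the equal-risk window fractions
#'
#' Lower / equal / greater slices in green / grey / red, angles proportional
#' to the fractions.
#'
#' @param wf a `ware_window` (or equivalent list with `lower`, `equal`,
#'   `greater`, `half_width`).
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_window_pie <- function(wf, title = "Relative risk") {
  slices <- data.frame(
    part = factor(c("lower", "equal", "greater"),
                  levels = c("lower", "equal", "greater")),
    fraction = c(wf$lower, wf$equal, wf$greater)
  )
  ggplot2::ggplot(slices,
                  ggplot2::aes(x = "", y = .data$fraction,
                               fill = .data$part)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::scale_fill_manual(values = c(lower = "darkgreen",
                                          equal = "grey60",
                                          greater = "red")) +
    ggplot2::labs(title = title,
                  subtitle = sprintf("equal = within +/-%.2f OR",
                                     wf$half_width),
                  fill = NULL, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
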