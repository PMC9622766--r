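#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a depth-distribution curve
#'
#' Stained area per depth bin against depth below the basal epithelial
#' layer, with the P90 depth marked.
#'
#' @param object a [depth_profile()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.depth_profile <- function(object, ...) {
  d <- tidy(object)
  d$depth_um <- (d$bin_lo_um + d$bin_hi_um) / 2
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$depth_um,
                                       y = .data$area_um2)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "depth below basal layer (µm)",
                  y = "stained area per bin (µm²)",
                  title = sprintf("Depth distribution (%s dermis)",
                                  object$compartment)) +
    ggplot2::theme_minimal()
  if (object$p90_defined)
    p <- p + ggplot2::geom_vline(xintercept = object$p90_um,
                                 linetype = "dashed") +
      ggplot2::annotate("text", x = object$p90_um, y = max(d$area_um2),
                        label = sprintf("P90 = %.0f µm", object$p90_um),
                        hjust = -0.05, vjust = 1, size = 3)
  p
}

#' Plot an ICG clearance curve
#'
#' ROI mean fluorescence intensity against time, one line per animal and
#' limb, with the 1-5 h AUC window shaded.
#'
#' @param object a [clearance_series()] (rows from several series can be
#'   bound together).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.clearance_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_h, y = .data$mean_intensity,
                               color = .data$limb,
                               group = interaction(.data$animal_id,
                                                   .data$limb))) +
    ggplot2::annotate("rect", xmin = 1, xmax = 5, ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time after injection (h)",
                  y = "ROI mean intensity (a.u.)",
                  title = "ICG clearance (shaded: 1-5 h AUC window)") +
    ggplot2::theme_minimal()
}

#' Plot a binwise curve comparison
#'
#' Per-bin Mann-Whitney p-values along depth, on a -log10 scale, with the
#' 0.05 line drawn.
#'
#' @param object a [compare_profiles_pointwise()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.curve_comparison <- function(object, ...) {
  d <- tidy(object)
  d$depth_um <- (d$bin_lo_um + d$bin_hi_um) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$depth_um,
                                  y = -log10(.data$p))) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = "depth below basal layer (µm)",
                  y = expression(-log[10](p)),
                  title = "Binwise Mann-Whitney comparison") +
    ggplot2::theme_minimal()
}

#' Plot scar indices per compartment
#'
#' @param object a [scar_index()] result (rows from several sections can be
#'   bound together, with an extra grouping column mapped via `fill`).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scar_index_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$compartment,
                                       y = .data$scar_index)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "scar index (thick/thin fiber area)",
                  title = "Collagen scar index") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
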