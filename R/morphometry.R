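#' Normalize an operated-paw thickness to its contralateral control
#'
#' The swelling readout of the hind-limb lymphedema model: the operated-paw
#' thickness `T` expressed as a percentage of the untreated contralateral paw
#' `Tc`, i.e. `(T / Tc) * 100`.  100 means no swelling; 300 a three-fold
#' thickening.  The ratio is unit-free, so any consistent length unit works.
#'
#' @param T_mm operated (lymphedematous) paw thickness.
#' @param Tc_mm contralateral control paw thickness, `> 0`.
#' @return `(T / Tc) * 100`; vectorized.
#' @export
normalize_paw <- function(T_mm, Tc_mm) {
  if (any(!is.finite(Tc_mm)) || any(Tc_mm <= 0))
    stop("`Tc_mm` must be positive", call. = FALSE)
  (T_mm / Tc_mm) * 100
}

#' Measure the thickness of a tissue band at independent sites
#'
#' Emulates caliper-style layer morphometry on a segmented epidermal or
#' dermal band: the band's long axis is found by principal components of the
#' pixel coordinates, measurement stations are spread evenly along it (with
#' optional random jitter inside each station's stratum), and at each station
#' the band extent perpendicular to the long axis is measured in
#' micrometers.  Five independent measurements is the conventional design.
#'
#' @param layer_mask logical/binary matrix; `TRUE` inside the band.
#' @param pixel_size_um pixel size, micrometers.
#' @param n_sites number of measurement stations (default 5).
#' @param seed integer seed for the jitter.
#' @param jitter fraction of a stratum width over which stations are
#'   jittered (0 = perfectly even spacing).
#' @param station_halfwidth_px half-width of the pixel slab pooled at each
#'   station, along the band axis.
#' @return A `layer_thickness_result`: tibble `measurements` (site,
#'   `thickness_um`) plus `median_um` and `iqr_um`.
#' @export
layer_thickness <- function(layer_mask, pixel_size_um, n_sites = 5L,
                            seed = 1L, jitter = 0, station_halfwidth_px = 2) {
  m <- as.matrix(layer_mask) > 0
  if (!any(m)) stop("`layer_mask` is empty", call. = FALSE)
  if (n_sites < 1L) stop("`n_sites` must be >= 1", call. = FALSE)
  idx <- which(m, arr.ind = TRUE)
  xy <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  if (nrow(xy) < 4L || stats::sd(xy[, 1]) + stats::sd(xy[, 2]) == 0)
    stop("`layer_mask` is degenerate (no extent)", call. = FALSE)
  ctr <- colMeans(xy)
  pc <- eigen(stats::cov(xy), symmetric = TRUE)
  axis_long <- pc$vectors[, 1]
  axis_perp <- pc$vectors[, 2]
  along <- (xy[, 1] - ctr[1]) * axis_long[1] + (xy[, 2] - ctr[2]) * axis_long[2]
  across <- (xy[, 1] - ctr[1]) * axis_perp[1] + (xy[, 2] - ctr[2]) * axis_perp[2]
  rng <- range(along)
  if (diff(rng) <= 0)
    stop("`layer_mask` is degenerate: band has no length", call. = FALSE)
  set.seed(seed)
  stratum <- diff(rng) / n_sites
  stations <- rng[1] + (seq_len(n_sites) - 0.5) * stratum +
    stats::runif(n_sites, -0.5, 0.5) * jitter * stratum
  thickness <- vapply(stations, function(s) {
    sel <- abs(along - s) <= station_halfwidth_px
    if (!any(sel)) return(NA_real_)
    (max(across[sel]) - min(across[sel]) + 1) * pixel_size_um
  }, 0)
  if (all(is.na(thickness)))
    stop("`layer_mask` is fragmented: no pixels at any measurement station",
         call. = FALSE)
  out <- structure(
    list(measurements = tibble::tibble(site = seq_len(n_sites),
                                       thickness_um = thickness),
         median_um = stats::median(thickness, na.rm = TRUE),
         iqr_um = stats::IQR(thickness, na.rm = TRUE),
         n_sites = n_sites, pixel_size_um = pixel_size_um),
    class = "layer_thickness_result")
  out
}

#' @export
print.layer_thickness_result <- function(x, ...) {
  cat(sprintf("<layer_thickness> %d sites: median %.4g um (IQR %.3g)\n",
              x$n_sites, x$median_um, x$iqr_um))
  invisible(x)
}

#' Median fold change between two groups of measurements
#'
#' `median(ld) / median(control)`, the summary used to report how many-fold a
#' stained area (or any other readout) increases in lymphedematous tissue
#' over its control.  Medians, not means, to match the nonparametric
#' reporting convention (median with interquartile range).
#'
#' @param ld_values numeric vector for the affected group.
#' @param control_values numeric vector for the control group.
#' @return The fold change; `NA` (with a warning) when the control median is
#'   zero.
#' @export
fold_change <- function(ld_values, control_values) {
  if (length(ld_values) == 0L || length(control_values) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  mc <- stats::median(control_values)
  if (mc == 0) {
    warning("control median is zero: fold change undefined")
    return(NA_real_)
  }
  stats::median(ld_values) / mc
}
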