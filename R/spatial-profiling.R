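#' Depth map referenced to the basal epithelial layer
#'
#' For every pixel, the Euclidean distance (in micrometers) to the nearest
#' point of the basal-layer polyline.  Pixels on the epidermal side of the
#' layer are flagged excluded: depth profiling is defined within the dermis
#' only.  Distance is true nearest-point distance to the polyline segments,
#' not vertical drop, so a curved basal layer is handled correctly; a flat
#' polyline takes a closed-form fast path.
#'
#' @param image a [section_image()] with a non-degenerate `basal_polyline`.
#' @return A `depth_map` object: `depth_um` (numeric `H x W` matrix),
#'   `excluded` (logical matrix, `TRUE` above the basal layer),
#'   `pixel_size_um`.
#' @export
depth_map <- function(image) {
  stopifnot(inherits(image, "section_image"))
  poly <- image$basal_polyline
  if (is.null(poly) || nrow(poly) < 2L)
    stop("degenerate basal polyline: at least two vertices are required",
         call. = FALSE)
  seg_len2 <- diff(poly[, 1])^2 + diff(poly[, 2])^2
  if (all(seg_len2 == 0))
    stop("degenerate basal polyline: all vertices coincide", call. = FALSE)
  h <- dim(image$pixels)[1]; w <- dim(image$pixels)[2]
  ps <- image$pixel_size_um
  X <- rep(0:(w - 1), each = h)
  Y <- rep(0:(h - 1), times = w)

  if (length(unique(poly[, 2])) == 1L &&
      min(poly[, 1]) <= 0 && max(poly[, 1]) >= w - 1) {
    d_px <- abs(Y - poly[1, 2])
  } else {
    d2 <- rep(Inf, h * w)
    for (s in seq_len(nrow(poly) - 1L)) {
      if (seg_len2[s] == 0) next
      ax <- poly[s, 1]; ay <- poly[s, 2]
      dx <- poly[s + 1, 1] - ax; dy <- poly[s + 1, 2] - ay
      t <- ((X - ax) * dx + (Y - ay) * dy) / seg_len2[s]
      t <- pmin(pmax(t, 0), 1)
      d2 <- pmin(d2, (X - ax - t * dx)^2 + (Y - ay - t * dy)^2)
    }
    d_px <- sqrt(d2)
  }
  y_at_x <- stats::approx(poly[, 1], poly[, 2], xout = 0:(w - 1),
                          rule = 2, ties = "ordered")$y
  excluded <- Y < y_at_x[X + 1L]
  structure(list(depth_um = matrix(d_px * ps, h, w),
                 excluded = matrix(excluded, h, w),
                 pixel_size_um = ps),
            class = "depth_map")
}

# step inverse of the cumulative bin-area curve: smallest bin start depth at
# which >= `q` of the total stained area has accumulated
p90_from_bins <- function(bin_lo, area, q = 0.9) {
  total <- sum(area)
  if (total <= 0) return(NA_real_)
  bin_lo[which(cumsum(area) >= q * total - 1e-12)[1]]
}

new_depth_profile <- function(bins, integrated, p90, compartment,
                              bin_width_um, pixel_size_um, n_pixels) {
  structure(list(bins = bins,
                 integrated_area_um2 = integrated,
                 p90_um = p90,
                 p90_defined = !is.na(p90),
                 compartment = compartment,
                 bin_width_um = bin_width_um,
                 pixel_size_um = pixel_size_um,
                 n_pixels = n_pixels,
                 distance_convention = "euclidean-to-polyline"),
            class = "depth_profile")
}

#' Depth-distribution profile of a stain mask
#'
#' Bins the stained pixels of a section by their depth below the basal
#' epithelial layer.  Each bin holds the stained area it contains (pixel
#' count times pixel area, um^2); the profile also carries the integrated
#' area (total stained area, the area under the depth-distribution curve) and
#' P90, the depth up to which 90% of the staining is detected.  P90 is the
#' empirical 0.9 quantile of the stained-pixel depths themselves, so it does
#' not depend on the bin grid; profiles recomputed from binned curves alone
#' (e.g. [mean_profile()]) use the step inverse of the cumulative bin areas.
#' Pixels flagged as epidermal in the depth map are never counted.
#'
#' @param stain a `stain_mask` from [binarize()] or a logical matrix.
#' @param dmap a [depth_map()] of the same section.
#' @param bin_width_um depth bin width, micrometers (default 10).
#' @return A `depth_profile` object; an empty mask yields an all-zero profile
#'   with `p90_defined = FALSE`.
#' @export
depth_profile <- function(stain, dmap, bin_width_um = 10) {
  stopifnot(inherits(dmap, "depth_map"))
  if (bin_width_um <= 0) stop("`bin_width_um` must be > 0", call. = FALSE)
  m <- if (inherits(stain, "stain_mask")) stain$mask else as.matrix(stain) > 0
  if (!identical(dim(m), dim(dmap$depth_um)))
    stop("mask and depth map dimensions differ", call. = FALSE)
  depths <- dmap$depth_um[m & !dmap$excluded]
  ps <- dmap$pixel_size_um
  if (length(depths) == 0L) {
    bins <- tibble::tibble(bin_lo_um = 0, bin_hi_um = bin_width_um,
                           area_um2 = 0)
    return(new_depth_profile(bins, 0, NA_real_, "whole", bin_width_um, ps, 0L))
  }
  n_bins <- max(1L, ceiling((max(depths) + 1e-9) / bin_width_um))
  edges <- seq(0, n_bins * bin_width_um, by = bin_width_um)
  idx <- pmin(pmax(findInterval(depths, edges, rightmost.closed = FALSE), 1L),
              n_bins)
  counts <- tabulate(idx, n_bins)
  bins <- tibble::tibble(bin_lo_um = edges[-length(edges)],
                         bin_hi_um = edges[-1],
                         area_um2 = counts * ps^2)
  p90 <- unname(stats::quantile(depths, 0.9, type = 1))
  new_depth_profile(bins, length(depths) * ps^2, p90, "whole",
                    bin_width_um, ps, length(depths))
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf(
    "<depth_profile> %s dermis: %d bins of %g um, integrated area %.4g um2, P90 %s\n",
    x$compartment, nrow(x$bins), x$bin_width_um, x$integrated_area_um2,
    if (x$p90_defined) sprintf("%.4g um", x$p90_um) else "undefined"))
  invisible(x)
}

#' Mean depth-distribution curve of several profiles
#'
#' Per-bin arithmetic mean of a set of depth profiles (the group-average
#' spatial distribution curve).  Profiles must share the bin width; shorter
#' profiles are zero-padded to the longest grid.  Integrated area and P90 are
#' recomputed from the mean curve (P90 by the step inverse of cumulative bin
#' area).
#'
#' @param profiles list of [depth_profile()] objects.
#' @return A `depth_profile`.
#' @export
mean_profile <- function(profiles) {
  if (length(profiles) == 0L)
    stop("`profiles` must contain at least one profile", call. = FALSE)
  stopifnot(all(vapply(profiles, inherits, TRUE, "depth_profile")))
  bw <- unique(vapply(profiles, function(p) p$bin_width_um, 0))
  if (length(bw) != 1L)
    stop("profiles use different bin widths; re-bin to a common grid first",
         call. = FALSE)
  n_max <- max(vapply(profiles, function(p) nrow(p$bins), 0L))
  areas <- vapply(profiles, function(p) {
    c(p$bins$area_um2, rep(0, n_max - nrow(p$bins)))
  }, numeric(n_max))
  mean_area <- rowMeans(matrix(areas, nrow = n_max))
  edges <- seq(0, n_max * bw, by = bw)
  bins <- tibble::tibble(bin_lo_um = edges[-length(edges)],
                         bin_hi_um = edges[-1], area_um2 = mean_area)
  comp <- unique(vapply(profiles, function(p) p$compartment, ""))
  new_depth_profile(bins, sum(mean_area),
                    p90_from_bins(bins$bin_lo_um, mean_area),
                    if (length(comp) == 1L) comp else "whole",
                    bw, profiles[[1]]$pixel_size_um,
                    NA_integer_)
}

#' Split a depth profile at the papillary/reticular junction
#'
#' Partitions the bins of a whole-dermis profile at the junction depth: bins
#' entirely above it are papillary, bins entirely below reticular, and a bin
#' straddling the junction is split pro rata by width.  The two integrated
#' areas sum exactly to the whole-dermis integrated area.
#'
#' @param profile a [depth_profile()].
#' @param junction_depth_um junction depth, micrometers below the basal
#'   layer.
#' @return A list with elements `papillary` and `reticular`, each a
#'   `depth_profile`.
#' @export
split_compartments <- function(profile, junction_depth_um) {
  stopifnot(inherits(profile, "depth_profile"))
  j <- junction_depth_um
  b <- profile$bins
  pap <- b[b$bin_hi_um <= j, ]
  ret <- b[b$bin_lo_um >= j, ]
  straddle <- b[b$bin_lo_um < j & b$bin_hi_um > j, ]
  if (nrow(straddle) == 1L) {
    frac <- (j - straddle$bin_lo_um) /
      (straddle$bin_hi_um - straddle$bin_lo_um)
    pap <- dplyr::bind_rows(pap, tibble::tibble(
      bin_lo_um = straddle$bin_lo_um, bin_hi_um = j,
      area_um2 = straddle$area_um2 * frac))
    ret <- dplyr::bind_rows(tibble::tibble(
      bin_lo_um = j, bin_hi_um = straddle$bin_hi_um,
      area_um2 = straddle$area_um2 * (1 - frac)), ret)
  }
  mk <- function(bins, comp) {
    if (nrow(bins) == 0L)
      bins <- tibble::tibble(bin_lo_um = numeric(0), bin_hi_um = numeric(0),
                             area_um2 = numeric(0))
    new_depth_profile(bins, sum(bins$area_um2),
                      p90_from_bins(bins$bin_lo_um, bins$area_um2),
                      comp, profile$bin_width_um, profile$pixel_size_um,
                      NA_integer_)
  }
  list(papillary = mk(pap, "papillary"), reticular = mk(ret, "reticular"))
}
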