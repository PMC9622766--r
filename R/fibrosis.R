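#' Classify birefringent collagen fibers by hue
#'
#' On picrosirius-red sections viewed through crossed polarizers, thick
#' (mainly type I) collagen fibers birefringe red-orange and thin (mainly
#' type III) fibers weakly green.  The image is converted to
#' hue/saturation/value; pixels bright and saturated enough (above the value
#' and saturation floors) are labeled thick if their hue falls in the
#' red-orange window and thin if in the green window.  Yellow hues between
#' the windows stay unassigned, as does the dark background.  The default
#' windows are the conventional picrosirius polarization bands; all
#' parameters are recorded in the result.
#'
#' @param image a [section_image()] (polarized-light capture) or RGB array.
#' @param hue_thick red-orange hue window(s), degrees on the hue circle; a
#'   2-column matrix of intervals or a single `c(lo, hi)`.  Default
#'   `[0, 50] U [340, 360]`.
#' @param hue_thin green hue window, degrees.  Default `[70, 160]`.
#' @param min_saturation,min_value floors in `[0, 1]` below which a pixel is
#'   unassigned (defaults 0.2 and 0.1).
#' @return A `fiber_masks` object: logical matrices `thick_mask` and
#'   `thin_mask` (always disjoint) plus the parameters used.
#' @export
classify_birefringence <- function(image,
                                   hue_thick = rbind(c(0, 50), c(340, 360)),
                                   hue_thin = c(70, 160),
                                   min_saturation = 0.2,
                                   min_value = 0.1) {
  px <- if (inherits(image, "section_image")) image$pixels else image
  hue_thick <- matrix(hue_thick, ncol = 2)
  hue_thin <- matrix(hue_thin, ncol = 2)
  for (wnd in list(hue_thick, hue_thin))
    if (any(wnd < 0) || any(wnd > 360) || any(wnd[, 1] >= wnd[, 2]))
      stop("hue windows must be increasing intervals within [0, 360]",
           call. = FALSE)
  in_windows <- function(hue, wnd) {
    hit <- rep(FALSE, length(hue))
    for (i in seq_len(nrow(wnd)))
      hit <- hit | (hue >= wnd[i, 1] & hue <= wnd[i, 2])
    hit
  }
  # reject overlapping thick/thin windows on a fine hue grid
  grid <- seq(0, 360, by = 0.5)
  if (any(in_windows(grid, hue_thick) & in_windows(grid, hue_thin)))
    stop("thick and thin hue windows overlap", call. = FALSE)

  h <- dim(px)[1]; w <- dim(px)[2]
  rgb <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
               as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  eligible <- hsv[2, ] >= min_saturation & hsv[3, ] >= min_value
  hue_deg <- hsv[1, ] * 360
  thick <- eligible & in_windows(hue_deg, hue_thick)
  thin <- eligible & in_windows(hue_deg, hue_thin) & !thick
  if (inherits(image, "section_image") && !is.null(image$tissue_mask)) {
    thick <- thick & as.vector(image$tissue_mask)
    thin <- thin & as.vector(image$tissue_mask)
  }
  structure(list(thick_mask = matrix(thick, h, w),
                 thin_mask = matrix(thin, h, w),
                 hue_thick = hue_thick, hue_thin = hue_thin,
                 min_saturation = min_saturation, min_value = min_value),
            class = "fiber_masks")
}

#' Scar index per dermal compartment
#'
#' The scar index is the thick/thin fiber area ratio, a measure of collagen
#' maturity and scarring fibrosis.  Thick and thin areas are summed
#' separately above (papillary) and below (reticular) the
#' papillary/reticular junction depth; epidermal pixels are excluded via the
#' depth map.  A compartment with zero thin-fiber area gets an undefined
#' (NA) index rather than an infinite one.
#'
#' @param masks a [classify_birefringence()] result.
#' @param dmap a [depth_map()] of the same section.
#' @param junction_depth_um junction depth, micrometers below the basal
#'   layer.
#' @return A tibble of class `scar_index_result` with one row per
#'   compartment: `compartment`, `thick_area_um2`, `thin_area_um2`,
#'   `scar_index`, `defined`.
#' @export
scar_index <- function(masks, dmap, junction_depth_um) {
  stopifnot(inherits(masks, "fiber_masks"), inherits(dmap, "depth_map"))
  if (!identical(dim(masks$thick_mask), dim(dmap$depth_um)))
    stop("fiber masks and depth map dimensions differ", call. = FALSE)
  ps <- dmap$pixel_size_um
  dermal <- !dmap$excluded
  pap <- dermal & dmap$depth_um < junction_depth_um
  ret <- dermal & dmap$depth_um >= junction_depth_um
  row_for <- function(region, name) {
    thick <- sum(masks$thick_mask & region) * ps^2
    thin <- sum(masks$thin_mask & region) * ps^2
    tibble::tibble(compartment = name, thick_area_um2 = thick,
                   thin_area_um2 = thin,
                   scar_index = if (thin > 0) thick / thin else NA_real_,
                   defined = thin > 0)
  }
  out <- dplyr::bind_rows(row_for(pap, "papillary"),
                          row_for(ret, "reticular"))
  class(out) <- c("scar_index_result", class(out))
  out
}
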