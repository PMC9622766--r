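#' Generate a synthetic stained skin section with exact ground truth
#'
#' Renders an 8-bit RGB section emulating an immunostained skin slide: a pale
#' epidermal/dermal background, a basal epithelial layer stored as a polyline
#' annotation, stain blobs placed at centroid depths drawn from the scene's
#' depth law, optional hair-follicle profiles in the papillary dermis, and
#' additive Gaussian pixel noise.  Blobs never cross the basal layer upward
#' into the epidermis.  The returned ground truth records the exact rendered
#' stained area (union of blob pixels times the pixel area), every drawn
#' centroid depth, and the empirical 90th percentile of those depths, so
#' parameter recovery by the segmentation and profiling stages can be scored
#' exactly.  The same spec (including its seed) always reproduces the same
#' image bit for bit.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements `image` (a [section_image()]) and `truth`
#'   (list with `total_stain_area_um2`, `depth_samples_um`, `true_p90_um`,
#'   `stain_pixel_count`).
#' @export
generate_skin_section <- function(spec) {
  validate_scene_spec(spec)
  set.seed(spec$seed)
  h <- spec$image_height_px; w <- spec$image_width_px
  ps <- spec$pixel_size_um
  basal_y <- basal_layer_y(spec)           # 0-based y per column
  poly <- basal_polyline_from_y(basal_y)

  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- spec$background_color[ch]

  # decorative follicles: neutral gray-brown ellipses in the papillary dermis
  if (spec$follicle_count > 0) {
    fx <- round(stats::runif(spec$follicle_count, 10, w - 11))
    for (i in seq_len(spec$follicle_count)) {
      fdepth_px <- round(stats::runif(1, 20, 60) / ps)
      fy <- round(basal_y[fx[i] + 1] + fdepth_px)
      rr <- pmax(1L, round(8 / ps)); rc <- pmax(1L, round(4 / ps))
      rows <- pmax(1L, fy - rr):pmin(h, fy + rr + 2L)
      cols <- pmax(1L, fx[i] - rc + 1L):pmin(w, fx[i] + rc + 1L)
      for (ch in 1:3) px[rows, cols, ch] <- c(185, 180, 178)[ch]
    }
  }

  depths <- numeric(0)
  stain_idx <- integer(0)
  if (spec$blob_count > 0) {
    r <- spec$blob_radius_px
    ri <- floor(r)
    off <- expand.grid(dy = -ri:ri, dx = -ri:ri)
    off <- off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
    placed <- place_blobs(spec, w, h, basal_y, r)
    cx <- placed$cx; cy <- placed$cy; depths <- placed$depths
    nb <- spec$blob_count; k <- nrow(off)
    rows0 <- rep(cy, each = k) + rep(off$dy, nb)   # 0-based
    cols0 <- rep(cx, each = k) + rep(off$dx, nb)
    keep <- rows0 >= 0 & rows0 < h & cols0 >= 0 & cols0 < w
    # clip to the dermal side of the basal layer
    keep <- keep & rows0 > basal_y[pmin(pmax(cols0, 0), w - 1) + 1L]
    stain_idx <- unique((rows0[keep] + 1L) + cols0[keep] * h)
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[stain_idx] <- spec$stain_color[ch]
      px[, , ch] <- plane
    }
  }

  if (spec$noise_sd > 0)
    px <- px + stats::rnorm(length(px), sd = spec$noise_sd)
  px[] <- pmin(pmax(round(px), 0), 255)
  storage.mode(px) <- "integer"

  image <- section_image(px, pixel_size_um = ps, basal_polyline = poly,
                         junction_depth_um = spec$junction_depth_um)
  truth <- list(
    total_stain_area_um2 = length(stain_idx) * ps^2,
    depth_samples_um = depths,
    true_p90_um = if (length(depths))
      unname(stats::quantile(depths, 0.9, type = 1)) else NA_real_,
    stain_pixel_count = length(stain_idx))
  list(image = image, truth = truth)
}

# 0-based basal-layer row per column (flat or gently undulating)
basal_layer_y <- function(spec) {
  base <- spec$epidermis_thickness_um / spec$pixel_size_um
  x <- seq_len(spec$image_width_px) - 1
  y <- base + spec$basal_wave_amplitude_px *
    sin(2 * pi * x / spec$basal_wave_period_px)
  pmax(y, 0)
}

basal_polyline_from_y <- function(basal_y) {
  w <- length(basal_y)
  if (all(basal_y == basal_y[1])) {
    xs <- c(0, w - 1)
  } else {
    xs <- unique(round(seq(0, w - 1, length.out = max(2, ceiling(w / 16)))))
  }
  cbind(x = xs, y = basal_y[xs + 1])
}

# sample blob centroids: x uniform, y from the depth law below the basal
# layer.  With `allow_overlap = FALSE`, centroids are rejection-sampled to a
# minimum separation of two radii (grid-hashed neighbor check), so every blob
# contributes its full pixel disc and the rendered area is exactly
# blob_count x disc size.
place_blobs <- function(spec, w, h, basal_y, r) {
  n <- spec$blob_count
  ri <- ceiling(r)
  draw <- function(m) {
    d <- sample_depths(spec$depth_distribution, m)
    x <- round(stats::runif(m, ri, w - 1 - ri))
    list(cx = x, cy = round(basal_y[x + 1L] + d / ps_local), depths = d)
  }
  ps_local <- spec$pixel_size_um
  if (spec$allow_overlap || n <= 1L) return(draw(n))
  cell <- 2 * r
  gx_max <- ceiling(w / cell) + 2L
  gy_max <- ceiling(h / cell) + 2L
  occ_x <- matrix(NA_real_, gy_max, gx_max)  # one accepted center per cell
  occ_y <- matrix(NA_real_, gy_max, gx_max)
  cx <- numeric(n); cy <- numeric(n); dep <- numeric(n)
  accepted <- 0L; tries <- 0L; max_tries <- 60L * n
  while (accepted < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- draw(1L)
    gx <- floor(cand$cx / cell) + 2L
    gy <- floor(cand$cy / cell) + 2L
    nb_x <- occ_x[(gy - 1):(gy + 1), (gx - 1):(gx + 1)]
    nb_y <- occ_y[(gy - 1):(gy + 1), (gx - 1):(gx + 1)]
    ok <- TRUE
    known <- !is.na(nb_x)
    if (any(known))
      ok <- all((nb_x[known] - cand$cx)^2 + (nb_y[known] - cand$cy)^2 >=
                  (2 * r)^2)
    if (ok && is.na(occ_x[gy, gx])) {
      accepted <- accepted + 1L
      cx[accepted] <- cand$cx; cy[accepted] <- cand$cy
      dep[accepted] <- cand$depths
      occ_x[gy, gx] <- cand$cx; occ_y[gy, gx] <- cand$cy
    }
  }
  if (accepted < n)
    stop("blobs cannot fit without overlap: placed ", accepted, " of ", n,
         " blobs of radius ", r, " px at minimum separation ", 2 * r,
         " px", call. = FALSE)
  list(cx = cx, cy = cy, depths = dep)
}

#' Generate a synthetic polarized-light Sirius red scene
#'
#' Emulates a picrosirius-red section viewed through crossed polarizers: fiber
#' pixels glow against a dark background, thick (mainly type I collagen)
#' fibers in a red-orange hue band and thin (mainly type III) fibers in a
#' green band.  `spec$blob_count` is read as the number of fiber pixels.  The
#' thick/thin assignment uses exact counts stratified by dermal compartment —
#' within the papillary and the reticular dermis separately, a fraction
#' `thick_fraction` (to integer rounding) of fiber pixels is thick — so the
#' generated per-compartment area ratio is controlled exactly and serves as
#' the oracle for [scar_index()] recovery.
#'
#' @param spec a [scene_spec()]; `blob_count` = number of fiber pixels,
#'   `depth_distribution` = law of fiber pixel depths.
#' @param thick_fraction fraction of fiber pixels labeled thick, in `[0, 1]`.
#' @return A list with `image` (a [section_image()]) and `truth` (per
#'   compartment and total thick/thin areas in um^2).
#' @export
generate_polarized_section <- function(spec, thick_fraction) {
  validate_scene_spec(spec)
  if (!is.numeric(thick_fraction) || thick_fraction < 0 || thick_fraction > 1)
    stop("`thick_fraction` must lie in [0, 1]", call. = FALSE)
  set.seed(spec$seed)
  h <- spec$image_height_px; w <- spec$image_width_px
  ps <- spec$pixel_size_um
  basal_y <- basal_layer_y(spec)
  poly <- basal_polyline_from_y(basal_y)

  n <- spec$blob_count
  depths <- sample_depths(spec$depth_distribution, n)
  cx <- round(stats::runif(n, 0, w - 1))
  cy <- round(basal_y[cx + 1L] + depths / ps)
  ok <- cy > basal_y[cx + 1L] & cy < h
  cx <- cx[ok]; cy <- cy[ok]; depths <- depths[ok]
  idx <- (cy + 1L) + cx * h
  dup <- duplicated(idx)
  cx <- cx[!dup]; cy <- cy[!dup]; depths <- depths[!dup]; idx <- idx[!dup]
  n <- length(idx)

  # compartment of each fiber pixel from its rendered position, so the truth
  # matches the geometry the depth map will measure
  pix_depth <- (cy - basal_y[cx + 1L]) * ps
  papillary <- pix_depth < spec$junction_depth_um
  thick <- logical(n)
  for (comp in c(TRUE, FALSE)) {
    sel <- which(papillary == comp)
    n_thick <- round(thick_fraction * length(sel))
    if (length(sel)) thick[sample(sel, n_thick)] <- TRUE
  }

  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- spec$background_color[ch]
  hue <- numeric(n)
  hue[thick]  <- stats::runif(sum(thick), 10, 40) / 360   # red-orange
  hue[!thick] <- stats::runif(sum(!thick), 90, 140) / 360 # green
  sat <- stats::runif(n, 0.75, 1)
  val <- stats::runif(n, 0.7, 1)
  rgb_cols <- grDevices::col2rgb(grDevices::hsv(hue, sat, val))
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[idx] <- rgb_cols[ch, ]
    px[, , ch] <- plane
  }
  if (spec$noise_sd > 0)
    px <- px + stats::rnorm(length(px), sd = spec$noise_sd)
  px[] <- pmin(pmax(round(px), 0), 255)
  storage.mode(px) <- "integer"

  image <- section_image(px, pixel_size_um = ps, basal_polyline = poly,
                         junction_depth_um = spec$junction_depth_um)
  area <- function(sel) sum(sel) * ps^2
  truth <- list(
    thick_area_um2 = area(thick), thin_area_um2 = area(!thick),
    papillary = list(thick_area_um2 = area(thick & papillary),
                     thin_area_um2 = area(!thick & papillary)),
    reticular = list(thick_area_um2 = area(thick & !papillary),
                     thin_area_um2 = area(!thick & !papillary)),
    depth_samples_um = pix_depth)
  list(image = image, truth = truth)
}
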