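#' Depth distributions for synthetic stain placement
#'
#' Constructors for the depth laws used by [generate_skin_section()] to place
#' stain blob centroids below the basal epithelial layer.  `depth_uniform()`
#' draws uniformly on `[lo_um, hi_um]`, `depth_point()` puts all mass at a
#' single depth, and `depth_mixture()` mixes other depth laws with the given
#' weights.
#'
#' @param lo_um,hi_um uniform bounds, micrometers below the basal layer.
#' @param d_um fixed depth, micrometers.
#' @param ... component depth distributions for `depth_mixture()`.
#' @param weights mixing weights, recycled to the number of components and
#'   normalized to sum to one.
#' @return An object of class `depth_distribution`.
#' @export
depth_uniform <- function(lo_um, hi_um) {
  stopifnot(is.numeric(lo_um), is.numeric(hi_um), lo_um >= 0, hi_um >= lo_um)
  structure(list(type = "uniform", lo_um = lo_um, hi_um = hi_um),
            class = "depth_distribution")
}

#' @rdname depth_uniform
#' @export
depth_point <- function(d_um) {
  stopifnot(is.numeric(d_um), d_um >= 0)
  structure(list(type = "point", d_um = d_um), class = "depth_distribution")
}

#' @rdname depth_uniform
#' @export
depth_mixture <- function(..., weights = 1) {
  comps <- list(...)
  stopifnot(length(comps) >= 1,
            all(vapply(comps, inherits, TRUE, "depth_distribution")))
  w <- rep_len(weights, length(comps))
  structure(list(type = "mixture", components = comps, weights = w / sum(w)),
            class = "depth_distribution")
}

sample_depths <- function(dist, n) {
  if (n == 0L) return(numeric(0))
  switch(dist$type,
    uniform = stats::runif(n, dist$lo_um, dist$hi_um),
    point   = rep(dist$d_um, n),
    mixture = {
      comp <- sample.int(length(dist$components), n, replace = TRUE,
                         prob = dist$weights)
      out <- numeric(n)
      for (j in seq_along(dist$components)) {
        sel <- comp == j
        out[sel] <- sample_depths(dist$components[[j]], sum(sel))
      }
      out
    },
    stop("unknown depth distribution type: ", dist$type, call. = FALSE))
}

depth_range <- function(dist) {
  switch(dist$type,
    uniform = c(dist$lo_um, dist$hi_um),
    point   = c(dist$d_um, dist$d_um),
    mixture = range(unlist(lapply(dist$components, depth_range))))
}

#' Specification of a synthetic skin-section scene
#'
#' Collects every parameter of the synthetic generator: raster size, pixel
#' size, the thickness of the epidermis (which sets the basal-layer position),
#' the papillary/reticular junction depth, the number, radius, color and depth
#' law of the stain blobs, background color, additive Gaussian noise level and
#' the random seed.  Validation enforces the geometric invariants: the
#' epidermis ends above the junction, the junction lies inside the dermal
#' extent, the deepest blob fits inside the raster, and all colors are 8-bit.
#'
#' @param image_height_px,image_width_px raster size in pixels.
#' @param pixel_size_um pixel side length, micrometers (default 0.23, a
#'   common 20x whole-slide scanning resolution; synthetic scenes are usually
#'   generated at a coarser pixel size to keep rasters small).
#' @param epidermis_thickness_um epidermal band thickness; the basal layer sits
#'   at this depth from the top of the raster.
#' @param junction_depth_um papillary/reticular dermis boundary, micrometers
#'   below the basal layer.
#' @param blob_count number of stain blobs (for polarized scenes: number of
#'   fiber pixels).
#' @param blob_radius_px blob radius in pixels.
#' @param depth_distribution a [depth_uniform()], [depth_point()] or
#'   [depth_mixture()] giving the law of blob centroid depths.
#' @param stain_color,background_color RGB triples in `[0, 255]`.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (8-bit units), applied per channel and clipped to `[0, 255]`.
#' @param follicle_count number of decorative hair-follicle profiles rendered
#'   in the papillary dermis (neutral-toned; never segmented as stain).
#' @param allow_overlap may stain blobs overlap?  When `FALSE`, centroids are
#'   placed by rejection sampling with a minimum separation of two radii and
#'   generation fails if the scene cannot accommodate them.
#' @param basal_wave_amplitude_px,basal_wave_period_px amplitude and period of
#'   a gentle sinusoidal undulation of the basal layer (0 = flat).
#' @param seed integer random seed.
#' @return A validated `scene_spec` object.
#' @export
scene_spec <- function(image_height_px, image_width_px,
                       pixel_size_um = 0.23,
                       epidermis_thickness_um,
                       junction_depth_um,
                       blob_count,
                       blob_radius_px = 2,
                       depth_distribution,
                       stain_color = c(150, 60, 40),
                       background_color = c(235, 228, 230),
                       noise_sd = 0,
                       follicle_count = 0,
                       allow_overlap = TRUE,
                       basal_wave_amplitude_px = 0,
                       basal_wave_period_px = 200,
                       seed = 1L) {
  spec <- list(image_height_px = as.integer(image_height_px),
               image_width_px = as.integer(image_width_px),
               pixel_size_um = pixel_size_um,
               epidermis_thickness_um = epidermis_thickness_um,
               junction_depth_um = junction_depth_um,
               blob_count = as.integer(blob_count),
               blob_radius_px = blob_radius_px,
               depth_distribution = depth_distribution,
               stain_color = stain_color,
               background_color = background_color,
               noise_sd = noise_sd,
               follicle_count = as.integer(follicle_count),
               allow_overlap = isTRUE(allow_overlap),
               basal_wave_amplitude_px = basal_wave_amplitude_px,
               basal_wave_period_px = basal_wave_period_px,
               seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (image_height_px <= 0 || image_width_px <= 0)
      stop("image dimensions must be positive", call. = FALSE)
    if (pixel_size_um <= 0)
      stop("`pixel_size_um` must be positive", call. = FALSE)
    if (blob_count < 0) stop("`blob_count` must be >= 0", call. = FALSE)
    if (blob_radius_px <= 0)
      stop("`blob_radius_px` must be positive", call. = FALSE)
    if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
    for (col in list(stain_color, background_color))
      if (length(col) != 3L || any(col < 0) || any(col > 255))
        stop("colors must be RGB triples in [0, 255]^3", call. = FALSE)
    dermis_extent_um <-
      (image_height_px - 1 - epidermis_thickness_um / pixel_size_um) *
      pixel_size_um
    if (epidermis_thickness_um <= 0)
      stop("`epidermis_thickness_um` must be positive", call. = FALSE)
    if (epidermis_thickness_um >= junction_depth_um)
      stop("`epidermis_thickness_um` must be smaller than ",
           "`junction_depth_um`", call. = FALSE)
    if (junction_depth_um <= 0 || junction_depth_um > dermis_extent_um)
      stop("`junction_depth_um` must lie inside the dermal extent (",
           round(dermis_extent_um, 1), " um)", call. = FALSE)
    if (blob_count > 0) {
      rng <- depth_range(depth_distribution)
      if (rng[2] + blob_radius_px * pixel_size_um > dermis_extent_um)
        stop("depth distribution exceeds the dermal extent: deepest blob at ",
             round(rng[2], 1), " um (+ radius) vs extent ",
             round(dermis_extent_um, 1), " um", call. = FALSE)
    }
  })
  invisible(spec)
}

#' Default control-skin scene
#'
#' A ready-made [scene_spec()] emulating a control (non-lymphedematous) skin
#' section: lymphatic-capillary-like blobs confined to the papillary dermis
#' (depths uniform on 40-320 um, below a 350 um papillary/reticular junction),
#' scattered around a few hair follicles.  In control skin the 90th depth
#' percentile of such a profile sits in the 225-300 um range.
#'
#' @param blob_count number of blobs (default 5000).
#' @param seed random seed (default 7).
#' @param noise_sd additive pixel noise (default 0).
#' @param ... further overrides passed to [scene_spec()].
#' @return A `scene_spec`.
#' @export
control_scene_spec <- function(blob_count = 5000, seed = 7, noise_sd = 0, ...) {
  args <- list(image_height_px = 220, image_width_px = 1500,
               pixel_size_um = 2,
               epidermis_thickness_um = 20,
               junction_depth_um = 350,
               blob_count = blob_count,
               blob_radius_px = 1.5,
               depth_distribution = depth_uniform(40, 320),
               follicle_count = 6,
               noise_sd = noise_sd,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(scene_spec, args)
}

#' Default polarized-light scene
#'
#' A [scene_spec()] preset for [generate_polarized_section()]: fiber pixels
#' on a near-black background, depths uniform over the upper 600 um of the
#' dermis with the papillary/reticular junction at 350 um.
#'
#' @param fiber_count number of fiber pixels (default 4000).
#' @param seed random seed.
#' @param ... overrides passed to [scene_spec()].
#' @return A `scene_spec`.
#' @export
polarized_scene_spec <- function(fiber_count = 4000, seed = 11, ...) {
  args <- list(image_height_px = 340, image_width_px = 800,
               pixel_size_um = 2,
               epidermis_thickness_um = 20,
               junction_depth_um = 350,
               blob_count = fiber_count,
               blob_radius_px = 1,
               depth_distribution = depth_uniform(5, 600),
               stain_color = c(255, 80, 20),
               background_color = c(6, 6, 6),
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(scene_spec, args)
}
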