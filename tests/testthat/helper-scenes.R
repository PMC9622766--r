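# Shared fixture builders: small synthetic scenes generated in code.

# compact stained scene; defaults keep rasters tiny for unit tests
tiny_scene <- function(blob_count = 50, noise_sd = 0, seed = 1,
                       depth = depth_uniform(40, 320),
                       height = 220, width = 400, ...) {
  args <- list(image_height_px = height, image_width_px = width,
               pixel_size_um = 2, epidermis_thickness_um = 20,
               junction_depth_um = 350, blob_count = blob_count,
               blob_radius_px = 1.5, depth_distribution = depth,
               noise_sd = noise_sd, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(scene_spec, args)
}

# flat-layer section image built directly (no generator), for oracle tests
flat_section <- function(h = 40, w = 60, basal_row = 5, ps = 1,
                         junction = NULL) {
  px <- array(200L, dim = c(h, w, 3))
  section_image(px, pixel_size_um = ps,
                basal_polyline = cbind(x = c(0, w - 1),
                                       y = c(basal_row, basal_row)),
                junction_depth_um = junction)
}

# brute-force point-to-segment distance (independent oracle for depth_map)
brute_polyline_dist <- function(px_x, px_y, poly) {
  dseg <- function(x, y, ax, ay, bx, by) {
    l2 <- (bx - ax)^2 + (by - ay)^2
    if (l2 == 0) return(sqrt((x - ax)^2 + (y - ay)^2))
    t <- min(max(((x - ax) * (bx - ax) + (y - ay) * (by - ay)) / l2, 0), 1)
    sqrt((x - ax - t * (bx - ax))^2 + (y - ay - t * (by - ay))^2)
  }
  vapply(seq_along(px_x), function(i) {
    min(vapply(seq_len(nrow(poly) - 1), function(s)
      dseg(px_x[i], px_y[i], poly[s, 1], poly[s, 2],
           poly[s + 1, 1], poly[s + 1, 2]), 0))
  }, 0)
}

# hand-built profiles with one value per bin, for curve-comparison tests
profiles_from_values <- function(values_per_section, bw = 10) {
  lapply(values_per_section, function(vals) {
    bins <- tibble::tibble(
      bin_lo_um = seq(0, by = bw, length.out = length(vals)),
      bin_hi_um = seq(bw, by = bw, length.out = length(vals)),
      area_um2 = vals)
    structure(list(bins = bins, integrated_area_um2 = sum(vals),
                   p90_um = NA_real_, p90_defined = FALSE,
                   compartment = "whole", bin_width_um = bw,
                   pixel_size_um = 1, n_pixels = NA_integer_,
                   distance_convention = "euclidean-to-polyline"),
              class = "depth_profile")
  })
}

# naive exhaustive Otsu: try every between-value cut, score the between-class
# variance directly from the raw values
brute_otsu <- function(v) {
  lev <- sort(unique(v))
  cuts <- (lev[-1] + lev[-length(lev)]) / 2
  score <- vapply(cuts, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    w0 * w1 * (mean(lo) - mean(hi))^2
  }, 0)
  cuts[which.max(score)]
}
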