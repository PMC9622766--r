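#' Generate a control/LD section cohort and recover the stain-area fold
#'
#' End-to-end parameter-recovery protocol for integrated stained area: a
#' cohort of control sections and a cohort of lymphedematous-limb (LD)
#' sections are generated whose true total stain areas differ by
#' `area_fold` (blob placement is non-overlapping, so the rendered area
#' ratio equals the blob-count ratio up to integer rounding); every section
#' is pushed through segmentation (excess color + automatic threshold),
#' depth mapping and depth profiling; and the median LD/control fold change
#' of the recovered integrated areas is returned alongside the generator
#' truth.
#'
#' @param area_fold true LD/control stain-area ratio (> 0).
#' @param n_per_group sections per arm (default 21, a typical per-condition
#'   image count).
#' @param control_blobs blobs per control section (default 120).
#' @param noise_sd pixel noise (default 5).
#' @param seed_base integer; section `i` of the control arm uses seed
#'   `seed_base + i`, the LD arm `seed_base + n_per_group + i`.
#' @param depth_control,depth_ld depth laws for the two arms (defaults:
#'   control uniform 40-320 um, LD uniform 40-600 um, i.e. staining
#'   infiltrating the reticular dermis).
#' @param image_height_px,image_width_px,pixel_size_um scene geometry; the
#'   raster must accommodate the deepest blob.
#' @return A list: `estimated_fold`, `true_fold` (from rendered ground-truth
#'   areas), `areas` (tibble: condition, section, integrated_area_um2,
#'   true_area_um2).
#' @export
cohort_fold_change <- function(area_fold, n_per_group = 21,
                               control_blobs = 120, noise_sd = 5,
                               seed_base = 0L,
                               depth_control = depth_uniform(40, 320),
                               depth_ld = depth_uniform(40, 600),
                               image_height_px = 340L,
                               image_width_px = 400L,
                               pixel_size_um = 2) {
  stopifnot(area_fold > 0, n_per_group >= 1)
  one <- function(n_blobs, dd, seed, cond, i) {
    spec <- scene_spec(
      image_height_px = image_height_px, image_width_px = image_width_px,
      pixel_size_um = pixel_size_um,
      epidermis_thickness_um = 20, junction_depth_um = 350,
      blob_count = n_blobs, blob_radius_px = 1.5,
      depth_distribution = dd, noise_sd = noise_sd,
      allow_overlap = FALSE, seed = seed)
    sec <- generate_skin_section(spec)
    stain <- segment_stain(sec$image, "R")
    prof <- depth_profile(stain, depth_map(sec$image))
    tibble::tibble(condition = cond, section = i,
                   integrated_area_um2 = prof$integrated_area_um2,
                   true_area_um2 = sec$truth$total_stain_area_um2)
  }
  seed_base <- as.integer(seed_base)
  ctl <- purrr::map_dfr(seq_len(n_per_group), function(i)
    one(control_blobs, depth_control, seed_base + i, "control", i))
  ld <- purrr::map_dfr(seq_len(n_per_group), function(i)
    one(round(control_blobs * area_fold), depth_ld,
        seed_base + n_per_group + i, "LD", i))
  areas <- dplyr::bind_rows(ctl, ld)
  list(estimated_fold = fold_change(ld$integrated_area_um2,
                                    ctl$integrated_area_um2),
       true_fold = fold_change(ld$true_area_um2, ctl$true_area_um2),
       areas = areas)
}
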