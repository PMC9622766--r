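test_that("empty and single-blob scenes give the trivial ground truths", {
  empty <- generate_skin_section(tiny_scene(blob_count = 0))
  expect_equal(empty$truth$total_stain_area_um2, 0)
  expect_length(empty$truth$depth_samples_um, 0)
  bg <- tiny_scene(blob_count = 0)$background_color
  expect_true(all(empty$image$pixels[, , 1] == bg[1]))

  one <- generate_skin_section(tiny_scene(blob_count = 1,
                                          depth = depth_point(50)))
  expect_equal(one$truth$depth_samples_um, 50)
  expect_equal(one$truth$true_p90_um, 50)
  expect_gt(one$truth$total_stain_area_um2, 0)
})

test_that("identical spec and seed reproduce images and truth bit for bit", {
  a <- generate_skin_section(tiny_scene(noise_sd = 8, seed = 99))
  b <- generate_skin_section(tiny_scene(noise_sd = 8, seed = 99))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  c <- generate_skin_section(tiny_scene(noise_sd = 8, seed = 100))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("ground-truth area equals rendered stained pixel count x pixel area", {
  sec <- generate_skin_section(tiny_scene(blob_count = 80, seed = 4))
  stain_color <- tiny_scene()$stain_color
  rendered <- sum(sec$image$pixels[, , 1] == stain_color[1] &
                  sec$image$pixels[, , 2] == stain_color[2] &
                  sec$image$pixels[, , 3] == stain_color[3])
  expect_equal(sec$truth$total_stain_area_um2,
               rendered * sec$image$pixel_size_um^2)
  expect_equal(sec$truth$stain_pixel_count, rendered)
})

test_that("blobs never cross the basal layer into the epidermis", {
  spec <- tiny_scene(blob_count = 200, depth = depth_uniform(0, 100),
                     seed = 12)
  sec <- generate_skin_section(spec)
  basal_row <- spec$epidermis_thickness_um / spec$pixel_size_um
  stained_rows <- which(sec$image$pixels[, , 1] == spec$stain_color[1],
                        arr.ind = TRUE)[, 1]
  expect_true(all(stained_rows - 1 > basal_row))
})

test_that("empirical P90 converges to the analytic 0.9 quantile at n = 10000", {
  spec <- tiny_scene(blob_count = 10000, depth = depth_uniform(0, 324.4),
                     height = 200, width = 2000, blob_radius_px = 1,
                     seed = 42)
  sec <- generate_skin_section(spec)
  # oracle: sort the drawn sample and take its 0.9 quantile
  sorted <- sort(sec$truth$depth_samples_um)
  oracle <- sorted[ceiling(0.9 * length(sorted))]
  expect_equal(sec$truth$true_p90_um, oracle)
  expect_lt(abs(oracle - 0.9 * 324.4) / (0.9 * 324.4), 0.02)
})

test_that("invalid scenes fail naming the violated constraint", {
  expect_error(tiny_scene(blob_count = 10, depth = depth_uniform(0, 5000)),
               "dermal extent")
  expect_error(scene_spec(image_height_px = 100, image_width_px = 100,
                          pixel_size_um = 2, epidermis_thickness_um = 20,
                          junction_depth_um = 350, blob_count = 5,
                          depth_distribution = depth_uniform(0, 50)),
               "junction")
  # more blobs than the raster can hold without overlap
  expect_error(generate_skin_section(
    tiny_scene(blob_count = 800, height = 60, width = 60,
               depth = depth_uniform(0, 60), junction_depth_um = 50,
               allow_overlap = FALSE)),
    "without overlap")
})

test_that("polarized scenes honor the requested thick fraction exactly", {
  all_thick <- generate_polarized_section(
    polarized_scene_spec(fiber_count = 500, seed = 2), 1)
  expect_equal(all_thick$truth$thin_area_um2, 0)

  half <- generate_polarized_section(
    polarized_scene_spec(fiber_count = 2000, seed = 3), 0.5)
  expect_equal(half$truth$thick_area_um2, half$truth$thin_area_um2)

  # oracle: the assigned hue labels, counted before rendering, fix the ratio
  q3 <- generate_polarized_section(
    polarized_scene_spec(fiber_count = 4000, seed = 5), 0.75)
  ratio <- q3$truth$thick_area_um2 / q3$truth$thin_area_um2
  expect_equal(ratio, 3, tolerance = 0.01)
})

test_that("ICG series match the closed-form trapezoid ground truth", {
  flat <- generate_icg_series(100, 0, noise_sd = 0)
  expect_equal(flat$truth$true_auc, 400)
  expect_equal(flat$series$mean_intensity, rep(100, 5))

  dec <- generate_icg_series(100, 0.2, noise_sd = 0)
  tp <- c(1, 3, 5); v <- 100 * exp(-0.2 * tp)
  expect_equal(dec$truth$true_auc,
               sum(diff(tp) * (v[-3] + v[-1]) / 2))

  steep <- generate_icg_series(100, 50, noise_sd = 0)
  expect_lt(steep$truth$true_auc, 1e-10)

  expect_error(generate_icg_series(100, 0.2, timepoints_h = c(0, 2, 4, 6)),
               "1 and 5")
})

test_that("paw cohorts honor group sizes and the swelling formula", {
  folds <- tibble::tibble(group = 1:4, day = 40L, fold = 1)
  coh <- generate_paw_cohort(c(8, 7, 11, 13), folds, noise_sd = 0, seed = 2)
  expect_equal(nrow(coh), 39)
  expect_equal(length(unique(coh$animal_id)), 39)
  expect_equal(coh$T_mm, coh$Tc_mm)

  folds3 <- dplyr::mutate(folds, fold = 3)
  coh3 <- generate_paw_cohort(c(8, 7, 11, 13), folds3, noise_sd = 0, seed = 2)
  expect_equal(normalize_paw(coh3$T_mm, coh3$Tc_mm), rep(300, 39))
})
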