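test_that("excess_color computes 2C - C1 - C2 and is gray-shift invariant", {
  px <- array(0L, dim = c(1, 3, 3))
  px[1, 1, ] <- c(255, 0, 0)
  px[1, 2, ] <- c(100, 100, 100)
  px[1, 3, ] <- c(10, 200, 30)
  expect_equal(excess_color(px, "R")[1, 1], 510)
  expect_equal(excess_color(px, "R")[1, 2], 0)
  expect_equal(excess_color(px, "G")[1, 2], 0)
  expect_equal(excess_color(px, "G")[1, 3], 360)

  set.seed(5)
  base <- array(sample(0:200, 60, TRUE), dim = c(4, 5, 3))
  shifted <- base + 30
  for (ch in c("R", "G", "B"))
    expect_equal(excess_color(shifted, ch), excess_color(base, ch))
})

test_that("auto_threshold separates two levels and ignores an all-ones mask", {
  map <- matrix(c(rep(0, 90), rep(510, 10)), 10, 10)
  thr <- auto_threshold(map)
  expect_gt(thr, 0); expect_lt(thr, 510)
  expect_identical(auto_threshold(map, mask = matrix(TRUE, 10, 10)), thr)
  expect_error(auto_threshold(matrix(7, 5, 5)), "degenerate")
})

test_that("auto_threshold matches the exhaustive between-class-variance search", {
  set.seed(101)
  # two Gaussian modes at 50 and 400 (sd 10): threshold lands between them
  v <- round(c(rnorm(400, 50, 10), rnorm(100, 400, 10)))
  map <- matrix(v, 25, 20)
  thr <- auto_threshold(map)
  expect_gt(thr, 80); expect_lt(thr, 370)
  expect_equal(map > thr, map > brute_otsu(v))

  # random integer histograms of varied shape
  for (i in 1:20) {
    set.seed(i)
    v <- sample(0:255, 300, TRUE, prob = runif(256)^2)
    if (length(unique(v)) < 2) next
    thr <- auto_threshold(matrix(v, 30, 10))
    expect_equal(matrix(v, 30, 10) > thr, matrix(v, 30, 10) > brute_otsu(v),
                 info = paste("histogram", i))
  }
})

test_that("binarize is strict, monotone, and respects sentinels", {
  map <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(sum(binarize(map, max(map))$mask), 0)
  expect_equal(sum(binarize(map, -1e300)$mask), 4)  # below-min sentinel
  expect_false(binarize(map, 2)$mask[2, 1])  # tie at threshold -> unstained

  set.seed(7)
  map <- matrix(runif(100, 0, 510), 10, 10)
  thresholds <- sort(runif(5, 0, 510))
  areas <- vapply(thresholds, function(t) sum(binarize(map, t)$mask), 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("segmentation recovers ground-truth area exactly without noise and within 5% at noise_sd 10", {
  clean <- generate_skin_section(tiny_scene(blob_count = 150, seed = 21))
  stain <- segment_stain(clean$image, "R")
  expect_equal(sum(stain$mask) * clean$image$pixel_size_um^2,
               clean$truth$total_stain_area_um2)

  noisy <- generate_skin_section(tiny_scene(blob_count = 150, seed = 21,
                                            noise_sd = 10))
  stain_n <- segment_stain(noisy$image, "R")
  est <- sum(stain_n$mask) * noisy$image$pixel_size_um^2
  expect_lt(abs(est - noisy$truth$total_stain_area_um2) /
              noisy$truth$total_stain_area_um2, 0.05)
})

test_that("manual corrections apply set arithmetic and flag the mask", {
  sec <- generate_skin_section(tiny_scene(blob_count = 30, seed = 3))
  stain <- segment_stain(sec$image, "R")
  dims <- dim(stain$mask)

  same <- apply_manual_correction(stain)
  expect_identical(same$mask, stain$mask)
  expect_false(same$manually_corrected)

  gone <- apply_manual_correction(stain, remove_mask = stain$mask)
  expect_equal(sum(gone$mask), 0)
  expect_true(gone$manually_corrected)

  add <- matrix(FALSE, dims[1], dims[2])
  free <- which(!stain$mask)[1:10]
  add[free] <- TRUE
  grown <- apply_manual_correction(stain, add_mask = add)
  expect_equal(sum(grown$mask), sum(stain$mask) + 10)

  both <- add
  expect_error(apply_manual_correction(stain, add_mask = both,
                                       remove_mask = both), "ambiguous")
})
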