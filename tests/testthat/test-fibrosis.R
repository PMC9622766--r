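test_that("hue classification assigns pure colors and rejects dark pixels", {
  px <- array(0L, dim = c(1, 3, 3))
  px[1, 1, ] <- c(255, 0, 0)   # hue 0: red-orange window
  px[1, 2, ] <- c(0, 255, 0)   # hue 120: green window
  px[1, 3, ] <- c(5, 5, 5)     # below the value floor
  fm <- classify_birefringence(px)
  expect_true(fm$thick_mask[1, 1]); expect_false(fm$thin_mask[1, 1])
  expect_true(fm$thin_mask[1, 2]); expect_false(fm$thick_mask[1, 2])
  expect_false(fm$thick_mask[1, 3] || fm$thin_mask[1, 3])
})

test_that("overlapping hue windows are rejected at validation", {
  expect_error(classify_birefringence(array(0L, c(1, 1, 3)),
                                      hue_thick = c(0, 100),
                                      hue_thin = c(70, 160)),
               "overlap")
})

test_that("classification is invariant to darkening above the value floor", {
  sec <- generate_polarized_section(polarized_scene_spec(fiber_count = 1500,
                                                         seed = 6), 0.6)
  fm1 <- classify_birefringence(sec$image)
  dark <- sec$image
  dark$pixels <- array(as.integer(round(sec$image$pixels * 0.6)),
                       dim = dim(sec$image$pixels))
  fm2 <- classify_birefringence(dark$pixels)
  expect_identical(fm1$thick_mask, fm2$thick_mask)
  expect_identical(fm1$thin_mask, fm2$thin_mask)
})

test_that("thick and thin masks are always disjoint", {
  for (seed in c(1, 2)) {
    sec <- generate_polarized_section(
      polarized_scene_spec(fiber_count = 1000, seed = seed), 0.4)
    fm <- classify_birefringence(sec$image)
    expect_equal(sum(fm$thick_mask & fm$thin_mask), 0)
  }
})

test_that("scar index recovers generated fiber composition per compartment", {
  # equal areas -> index 1
  half <- generate_polarized_section(polarized_scene_spec(seed = 3), 0.5)
  si <- scar_index(classify_birefringence(half$image),
                   depth_map(half$image), 350)
  expect_equal(si$scar_index, c(1, 1), tolerance = 0.02)

  # thick_fraction 0.75 -> index 3 up to rendering quantization
  q3 <- generate_polarized_section(polarized_scene_spec(seed = 5), 0.75)
  si3 <- scar_index(classify_birefringence(q3$image),
                    depth_map(q3$image), 350)
  truth_ratio <- q3$truth$papillary$thick_area_um2 /
    q3$truth$papillary$thin_area_um2
  expect_equal(si3$scar_index[si3$compartment == "papillary"],
               truth_ratio, tolerance = 0.02)
  expect_equal(si3$scar_index[si3$compartment == "papillary"], 3,
               tolerance = 0.05)

  # zero thin fibers -> undefined, not infinite
  all_thick <- generate_polarized_section(
    polarized_scene_spec(fiber_count = 800, seed = 9), 1)
  siu <- scar_index(classify_birefringence(all_thick$image),
                    depth_map(all_thick$image), 350)
  expect_false(any(siu$defined))
  expect_true(all(is.na(siu$scar_index)))
})

test_that("a generated LD/control pair at scar-index ratio 1.5 is recovered", {
  ctl <- generate_polarized_section(polarized_scene_spec(seed = 11), 0.5)
  ld <- generate_polarized_section(polarized_scene_spec(seed = 1100), 0.6)
  si_of <- function(s)
    scar_index(classify_birefringence(s$image), depth_map(s$image), 350)
  r <- si_of(ld)$scar_index[1] / si_of(ctl)$scar_index[1]
  expect_equal(r, 1.5, tolerance = 0.05)
})
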