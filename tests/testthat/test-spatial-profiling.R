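test_that("depth map distances are exact for a flat basal layer", {
  img <- flat_section(h = 120, w = 30, basal_row = 0, ps = 0.23)
  dm <- depth_map(img)
  expect_equal(dm$depth_um[101, 15], 100 * 0.23)  # row 100 (0-based), 23 um
  expect_equal(dm$depth_um[1, 7], 0)              # on the polyline
  expect_false(dm$excluded[1, 7])
  expect_true(all(dm$depth_um >= 0))
})

test_that("depth map equals brute-force point-to-segment distance on jagged polylines", {
  set.seed(42)
  for (rep in 1:8) {
    h <- 40; w <- 50
    nv <- sample(3:6, 1)
    poly <- cbind(x = sort(runif(nv, 0, w - 1)), y = runif(nv, 2, 12))
    px <- array(150L, dim = c(h, w, 3))
    img <- section_image(px, pixel_size_um = 1.7, basal_polyline = poly)
    dm <- depth_map(img)
    pts <- cbind(x = sample(0:(w - 1), 25, TRUE),
                 y = sample(0:(h - 1), 25, TRUE))
    expected <- brute_polyline_dist(pts[, 1], pts[, 2], poly) * 1.7
    got <- dm$depth_um[cbind(pts[, 2] + 1, pts[, 1] + 1)]
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("epidermal pixels are flagged excluded and a degenerate polyline fails", {
  img <- flat_section(h = 30, w = 20, basal_row = 10)
  dm <- depth_map(img)
  expect_true(all(dm$excluded[1:10, ]))
  expect_false(any(dm$excluded[11:30, ]))

  bad <- flat_section()
  bad$basal_polyline <- cbind(x = c(3, 3), y = c(4, 4))
  expect_error(depth_map(bad), "degenerate")
})

test_that("depth profiles bin area correctly and place P90 at the staining mass", {
  img <- flat_section(h = 100, w = 50, basal_row = 0, ps = 1)
  dm <- depth_map(img)
  mask <- matrix(FALSE, 100, 50)
  mask[51, ] <- TRUE                      # all staining at depth 50 um
  prof <- depth_profile(mask, dm, bin_width_um = 10)
  nz <- prof$bins[prof$bins$area_um2 > 0, ]
  expect_equal(nrow(nz), 1)
  expect_equal(nz$bin_lo_um, 50)
  expect_equal(prof$p90_um, 50)
  expect_equal(prof$integrated_area_um2, 50)

  # area arithmetic at scanner resolution
  img2 <- flat_section(h = 60, w = 60, basal_row = 0, ps = 0.23)
  dm2 <- depth_map(img2)
  mask2 <- matrix(FALSE, 60, 60)
  mask2[which(!dm2$excluded)[1:1000]] <- TRUE
  prof2 <- depth_profile(mask2, dm2)
  expect_equal(prof2$integrated_area_um2, 1000 * 0.0529, tolerance = 1e-6)
})

test_that("profile P90 tracks the sorted-sample quantile of uniform staining", {
  spec <- tiny_scene(blob_count = 10000, depth = depth_uniform(0, 324.4),
                     height = 200, width = 2000, blob_radius_px = 1,
                     seed = 42)
  sec <- generate_skin_section(spec)
  stain <- segment_stain(sec$image, "R")
  prof <- depth_profile(stain, depth_map(sec$image))
  oracle <- sort(sec$truth$depth_samples_um)
  oracle <- oracle[ceiling(0.9 * length(oracle))]
  expect_lt(abs(prof$p90_um - oracle) / oracle, 0.02)
})

test_that("empty masks yield a zero profile with undefined P90, not an error", {
  img <- flat_section()
  prof <- depth_profile(matrix(FALSE, 40, 60), depth_map(img))
  expect_equal(prof$integrated_area_um2, 0)
  expect_false(prof$p90_defined)
})

test_that("mean_profile is idempotent and follows the cumulative-mass convention", {
  img <- flat_section(h = 400, w = 20, basal_row = 0, ps = 1)
  dm <- depth_map(img)
  m1 <- matrix(FALSE, 400, 20); m1[106, ] <- TRUE  # mass at 105 um
  m2 <- matrix(FALSE, 400, 20); m2[306, ] <- TRUE  # mass at 305 um
  p1 <- depth_profile(m1, dm); p2 <- depth_profile(m2, dm)

  expect_equal(mean_profile(list(p1))$bins$area_um2, p1$bins$area_um2)
  expect_equal(mean_profile(list(p1, p1))$integrated_area_um2,
               p1$integrated_area_um2)

  # two equal point masses: 90% of cumulative area is reached in the deep bin
  m <- mean_profile(list(p1, p2))
  expect_equal(m$p90_um, 300)
  expect_equal(m$integrated_area_um2,
               (p1$integrated_area_um2 + p2$integrated_area_um2) / 2)
  expect_error(mean_profile(list()), "at least one")
})

test_that("compartment split conserves area and honors bin-edge junctions", {
  sec <- generate_skin_section(tiny_scene(blob_count = 200, seed = 8,
                                          depth = depth_uniform(0, 600),
                                          height = 340))
  prof <- depth_profile(segment_stain(sec$image, "R"),
                        depth_map(sec$image))
  for (j in c(155, 350, 204.3)) {
    parts <- split_compartments(prof, j)
    expect_equal(parts$papillary$integrated_area_um2 +
                   parts$reticular$integrated_area_um2,
                 prof$integrated_area_um2, tolerance = 1e-12)
  }
  beyond <- split_compartments(prof, max(prof$bins$bin_hi_um) + 50)
  expect_equal(beyond$reticular$integrated_area_um2, 0)

  # uniform curve, junction at 25% of the range -> 25% of the area papillary
  img <- flat_section(h = 401, w = 10, basal_row = 0, ps = 1)
  dmu <- depth_map(img)
  mu <- matrix(FALSE, 401, 10); mu[2:401, ] <- TRUE  # uniform over (0, 400]
  pu <- depth_profile(mu, dmu)
  parts <- split_compartments(pu, 100)
  expect_equal(parts$papillary$integrated_area_um2 /
                 pu$integrated_area_um2, 99 / 400)  # depths 1..99 of 1..400
})

test_that("depths scale linearly and areas quadratically with pixel size", {
  base <- tiny_scene(blob_count = 60, seed = 10)
  sec1 <- generate_skin_section(base)
  p1 <- depth_profile(segment_stain(sec1$image, "R"),
                      depth_map(sec1$image))
  sec2 <- sec1
  sec2$image$pixel_size_um <- base$pixel_size_um * 2
  p2 <- depth_profile(segment_stain(sec2$image, "R"),
                      depth_map(sec2$image))
  expect_equal(p2$p90_um, 2 * p1$p90_um)
  expect_equal(p2$integrated_area_um2, 4 * p1$integrated_area_um2)
})

test_that("P90 is robust to the bin grid", {
  sec <- generate_skin_section(tiny_scene(blob_count = 400, seed = 14))
  stain <- segment_stain(sec$image, "R")
  dm <- depth_map(sec$image)
  p5 <- depth_profile(stain, dm, bin_width_um = 5)
  p20 <- depth_profile(stain, dm, bin_width_um = 20)
  expect_lt(abs(p5$p90_um - p20$p90_um), 20)
})
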