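test_that("skeleton length is exact on axis-aligned and diagonal segments", {
  m <- matrix(0L, 5, 15); m[3, 3:13] <- 1L          # 1 x 11 horizontal
  expect_equal(skeleton_length(m, 0.1), 1.0)
  v <- t(m)                                          # vertical
  expect_equal(skeleton_length(v, 0.1), 1.0)
  d <- matrix(0L, 15, 15)
  for (i in 0:10) d[3 + i, 3 + i] <- 1L              # 11 px at 45 degrees
  expect_equal(skeleton_length(d, 0.1), 10 * sqrt(2) * 0.1)
  # single pixel: zero length; empty / multi-component: errors
  p <- matrix(0L, 3, 3); p[2, 2] <- 1L
  expect_equal(skeleton_length(p, 0.1), 0)
  expect_error(skeleton_length(matrix(0L, 3, 3), 0.1), "empty")
  p2 <- p; p2[1, 1] <- 1L; p2[3, 3] <- 1L  # diagonal chain is 8-connected
  expect_equal(max(cilimetry:::.cc_label8(p2)), 1L)
  p3 <- matrix(0L, 5, 5); p3[1, 1] <- 1L; p3[5, 5] <- 1L
  expect_error(skeleton_length(p3, 0.1), "components")
})

test_that("skeleton length tracks Euclidean length within the chamfer bias", {
  # the (1, sqrt 2) step weighting overestimates digitised straight lines by
  # up to ~8% at intermediate angles (worst near 22.5 degrees); axis-aligned
  # and diagonal directions are exact
  for (theta in c(15, 22.5, 30, 60, 75) * pi / 180) {
    m <- segment_mask(40, theta)
    skel_len <- skeleton_length(m, 1)
    expect_lt(abs(skel_len - 40) / 40, 0.085)
  }
})

test_that("measurements scale correctly with pixel size", {
  set.seed(41)
  m <- disc_mask(30, 30, 15, 15, 6)
  img <- matrix(runif(900, 10, 50), 30, 30)
  a <- measure_objects(m, img, 0.1)
  b <- measure_objects(m, img, 0.3)
  expect_equal(b$length_um, 3 * a$length_um)
  expect_equal(b$major_axis_um, 3 * a$major_axis_um)
  expect_equal(b$area_um2, 9 * a$area_um2)
  expect_equal(b$area_px, a$area_px)
  expect_equal(b$mean_intensity, a$mean_intensity)
})

test_that("per-object measurements match an explicit accumulation oracle", {
  set.seed(42)
  img <- matrix(runif(48 * 48, 0, 255), 48, 48)
  mask <- matrix(rbinom(48 * 48, 1L, 0.3), 48, 48)
  labels <- split_touching_objects(mask, 4L)
  meas <- measure_objects(labels, img, 0.1)
  ref <- measure_oracle(labels, img)
  expect_equal(meas$area_px, ref$area_px)
  expect_equal(meas$mean_intensity, ref$mean_intensity)
  expect_equal(meas$centroid_y, ref$centroid_y)
  expect_equal(meas$centroid_x, ref$centroid_x)
  expect_equal(meas$area_um2, ref$area_px * 0.01)
  # mean intensity bounded by the source image range
  expect_true(all(meas$mean_intensity >= min(img) &
                  meas$mean_intensity <= max(img)))
  # path length cannot exceed total diagonal traversal
  expect_true(all(meas$length_um <= meas$area_px * 0.1 * sqrt(2)))
  # constants example: an 11-px segment of intensity 200
  seg <- matrix(0L, 5, 15); seg[3, 3:13] <- 1L
  flat <- matrix(200, 5, 15)
  one <- measure_objects(seg, flat, 0.1)
  expect_equal(one$area_px, 11L)
  expect_equal(one$mean_intensity, 200)
  expect_equal(one$length_um, 1.0)
  # empty label map: empty frame, not an error
  expect_equal(nrow(measure_objects(matrix(0L, 4, 4), matrix(0, 4, 4), 0.1)), 0)
  expect_error(measure_objects(matrix(0L, 4, 4), matrix(0, 5, 5), 0.1),
               "shapes")
})

test_that("major axis follows the regionprops ellipse convention", {
  # a filled axis-aligned rectangle 21 x 5: MajorAxisLength =
  # 2*sqrt(2)*sqrt(uxx + uyy + sqrt((uxx-uyy)^2)) with uxx = (w^2-1)/12 + 1/12
  m <- matrix(0L, 20, 40); m[8:12, 10:30] <- 1L
  meas <- measure_objects(m, matrix(1, 20, 40), 1)
  w <- 21; h <- 5
  uxx <- (w^2 - 1) / 12 + 1 / 12
  uyy <- (h^2 - 1) / 12 + 1 / 12
  expect_equal(meas$major_axis_um, 2 * sqrt(2) * sqrt(uxx + uyy + (uxx - uyy)))
})

test_that("incidence is the cilia-per-100-nuclei ratio", {
  expect_equal(compute_incidence(30, 100), 30)
  expect_equal(compute_incidence(0, 250), 0)
  expect_true(is.na(compute_incidence(3, 0)))
  expect_error(compute_incidence(-1, 10), "non-negative")
  set.seed(43)
  for (i in 1:25) {
    nc <- sample(0:400, 1); nn <- sample(1:400, 1)
    expect_equal(compute_incidence(nc, nn), nc / nn * 100)
  }
  # invariance to relabelling: incidence depends only on counts
  m <- matrix(0L, 10, 10); m[2, 2:4] <- 1L; m[7, 6:8] <- 1L
  lab <- split_touching_objects(m, 3L)
  relab <- lab
  relab[lab == 1L] <- 2L; relab[lab == 2L] <- 1L
  expect_equal(max(lab), max(relab))
})

test_that("field summaries aggregate measurements and attach QC flags", {
  meas <- data.frame(length_um = c(2, 4))
  s <- summarize_field(meas, n_nuclei = 10, image_id = "f1")
  expect_equal(s$n_cilia, 2)
  expect_equal(s$mean_length_um, 3)
  expect_equal(s$incidence_pct, 20)
  expect_equal(s$qc_flags, "")
  empty <- summarize_field(meas[0, , drop = FALSE], 10, "f2")
  expect_equal(empty$n_cilia, 0)
  expect_true(is.na(empty$mean_length_um))
  expect_equal(empty$incidence_pct, 0)
  none <- summarize_field(meas, 0, "f3")
  expect_true(is.na(none$incidence_pct))
  expect_match(none$qc_flags, "no_nuclei")
  multi <- summarize_field(data.frame(length_um = rep(1, 12)), 10, "f4")
  expect_gt(multi$incidence_pct, 100)  # reported, not clamped
  expect_match(multi$qc_flags, "multiciliation_or_oversegmentation")
})
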