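test_that("cilium paths have the requested arc length and curvature", {
  set.seed(61)
  # zero curvature: straight; end-to-end distance equals arc length
  p <- sample_cilium_path(4, curvature_max = 0, step_um = 0.05)
  expect_equal(attr(p, "arc_length_um"), 4)
  expect_equal(sqrt(sum((p[nrow(p), ] - p[1, ])^2)), 4)
  # arc length within half a step of the target
  for (len in c(2.13, 3.5, 5.97)) {
    q <- sample_cilium_path(len, 0.3, 0.05)
    seg <- sqrt(rowSums(diff(q)^2))
    expect_equal(sum(seg), attr(q, "arc_length_um"))
    expect_lt(abs(sum(seg) - len), 0.05 / 2 + 1e-9)
  }
  # curved path is shorter end-to-end than its arc length
  set.seed(62)
  c1 <- sample_cilium_path(5, 0.5, 0.05)
  expect_lt(sqrt(sum((c1[nrow(c1), ] - c1[1, ])^2)), 5)
  # same seed: identical vertices
  set.seed(63); a <- sample_cilium_path(3, 0.2, 0.05)
  set.seed(63); b <- sample_cilium_path(3, 0.2, 0.05)
  expect_identical(a, b)
  expect_error(sample_cilium_path(0, 0.1, 0.05), "positive")
  expect_error(sample_cilium_path(2, 0.1, 0), "positive")
})

test_that("rendered fields honour their configuration and ground truth", {
  cfg <- simulation_config(image_size_px = c(256, 256), n_nuclei = 8,
                           ciliation_probability = 0.5, seed = 64)
  f <- render_field(cfg)
  expect_s3_class(f$stack, "ImageStack")
  expect_identical(f$stack$channel_labels, c("ARL13B", "DAPI"))
  # truth is internally consistent
  expect_equal(f$truth$field$n_cilia, nrow(f$truth$cilia))
  expect_equal(f$truth$field$incidence_pct,
               f$truth$field$n_cilia / f$truth$field$n_nuclei * 100)
  expect_equal(length(f$truth$paths), nrow(f$truth$cilia))
  # polyline arc lengths match their truth records
  for (k in seq_along(f$truth$paths))
    expect_equal(sum(sqrt(rowSums(diff(f$truth$paths[[k]])^2))),
                 f$truth$cilia$true_length_um[k], tolerance = 1e-9)
  # same seed: identical field; different seed: different field
  g <- render_field(cfg)
  expect_identical(g$stack$pixels, f$stack$pixels)
  h <- render_field(cfg, seed = 65)
  expect_false(identical(h$stack$pixels, f$stack$pixels))
})

test_that("zero ciliation gives a background-only cilia channel", {
  cfg <- simulation_config(image_size_px = c(128, 128), n_nuclei = 5,
                           nucleus_radius_um = 1.5,
                           ciliation_probability = 0, psf_sigma_um = 0,
                           read_noise_sd = 0, shot_noise = FALSE, seed = 66)
  f <- render_field(cfg)
  expect_equal(f$truth$field$n_cilia, 0)
  expect_true(all(f$stack$pixels[, , 1, 1] == cfg$background_intensity))
  # with noise on, the channel fluctuates around the background
  cfg2 <- simulation_config(image_size_px = c(128, 128), n_nuclei = 5,
                            nucleus_radius_um = 1.5,
                            ciliation_probability = 0, psf_sigma_um = 0,
                            seed = 66)
  f2 <- render_field(cfg2)
  expect_equal(mean(f2$stack$pixels[, , 1, 1]), cfg2$background_intensity,
               tolerance = 0.02)
})

test_that("per-field incidence fluctuates around the Binomial mean", {
  cfg <- simulation_config(image_size_px = c(128, 128), n_nuclei = 4,
                           ciliation_probability = 0.6, psf_sigma_um = 0,
                           read_noise_sd = 0, shot_noise = FALSE,
                           nucleus_radius_um = 1.5, length_median_um = 2.0)
  inc <- vapply(1:300, function(s)
    render_field(cfg, seed = 5000 + s)$truth$field$incidence_pct, 0)
  # mean of 1200 Bernoulli(0.6) draws: within 2 points of 60% w.h.p.
  expect_lt(abs(mean(inc) - 60), 2)
})

test_that("simulated experiments land on disk deterministically", {
  cfgs <- list(
    WT = simulation_config(image_size_px = c(96, 96), n_nuclei = 3,
                           nucleus_radius_um = 1.5, length_median_um = 2.5),
    RP11 = simulation_config(image_size_px = c(96, 96), n_nuclei = 3,
                             nucleus_radius_um = 1.5, length_median_um = 1.8))
  d1 <- file.path(tempfile(), "run1")
  d2 <- file.path(tempfile(), "run2")
  e1 <- simulate_experiment(cfgs, n_fields = 3, seed = 42, out_dir = d1)
  e2 <- simulate_experiment(cfgs, n_fields = 3, seed = 42, out_dir = d2)
  # 2 groups x 3 fields: 6 images, 6 field-truth rows
  expect_equal(nrow(e1$manifest), 6)
  expect_equal(nrow(e1$truth_fields), 6)
  expect_true(all(file.exists(e1$manifest$path)))
  # byte-identical truth tables and images across reruns with one seed
  for (fn in c("truth_cilia.csv", "truth_fields.csv"))
    expect_identical(readBin(file.path(d1, fn), "raw", 1e6),
                     readBin(file.path(d2, fn), "raw", 1e6))
  for (i in seq_len(nrow(e1$manifest)))
    expect_identical(unname(tools::md5sum(e1$manifest$path[i])),
                     unname(tools::md5sum(e2$manifest$path[i])))
  expect_error(simulate_experiment(list(), 2, 1, tempfile()), "one group")
})

test_that("fields too crowded for the nuclei fail loudly", {
  cfg <- simulation_config(image_size_px = c(64, 64), n_nuclei = 40, seed = 1)
  expect_error(render_field(cfg), "too small")
})
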