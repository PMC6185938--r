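# Independent oracles and shared fixtures for the test suite. Everything here
# is deliberately written against the mathematical definitions, not against
# the package's own algorithms.

# shift a logical matrix by (dy, dx), padding with FALSE
shift_mat <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(FALSE, ny, nx)
  ys <- seq_len(ny) - dy
  xs <- seq_len(nx) - dx
  ok_y <- ys >= 1 & ys <= ny
  ok_x <- xs >= 1 & xs <= nx
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

# grow a seed set through a candidate set by repeated 8-neighbour dilation
# (fixed-point flood fill)
grow_from <- function(seeds, cand) {
  cur <- seeds & cand
  repeat {
    grown <- cur
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      grown <- grown | (shift_mat(cur, dy, dx) & cand)
    }
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

# hysteresis by definition: flood from strict-high seeds through strict-low
hysteresis_oracle <- function(img, low, high) {
  cur <- grow_from(img > high, img > low)
  matrix(as.integer(cur), nrow(img), ncol(img))
}

# 8-connected labelling by repeated single-seed flood fill
label_oracle <- function(mask) {
  mask <- mask != 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  next_id <- 0L
  while (any(mask & lab == 0L)) {
    seed <- matrix(FALSE, nrow(mask), ncol(mask))
    seed[which(mask & lab == 0L)[1L]] <- TRUE
    comp <- grow_from(seed, mask)
    next_id <- next_id + 1L
    lab[comp] <- next_id
  }
  lab
}

# per-label area / intensity-sum accumulation by explicit per-pixel loop
measure_oracle <- function(labels, intensity) {
  n <- max(labels)
  area <- integer(n); s <- numeric(n); sy <- numeric(n); sx <- numeric(n)
  for (x in seq_len(ncol(labels))) for (y in seq_len(nrow(labels))) {
    l <- labels[y, x]
    if (l > 0) {
      area[l] <- area[l] + 1L
      s[l] <- s[l] + intensity[y, x]
      sy[l] <- sy[l] + y
      sx[l] <- sx[l] + x
    }
  }
  data.frame(label = seq_len(n), area_px = area, mean_intensity = s / area,
             centroid_y = sy / area, centroid_x = sx / area)
}

# a filled disc mask
disc_mask <- function(ny, nx, cy, cx, r) {
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  matrix(as.integer((yy - cy)^2 + (xx - cx)^2 <= r^2), ny, nx)
}

# a 1-px straight segment mask of `len_px` pixel-steps at angle `theta`
# (radians, in (0, pi/2]) starting near the top-left corner
segment_mask <- function(len_px, theta, pad = 6) {
  n <- ceiling(len_px) + 2 * pad
  m <- matrix(0L, n, n)
  t <- seq(0, len_px, by = 0.25)
  ys <- round(pad + 1 + t * sin(theta))
  xs <- round(pad + 1 + t * cos(theta))
  m[cbind(ys, xs)] <- 1L
  m
}

# segmentation settings used on simulator output (derived from the imaging
# model, see the methods vignette):
# - noise-free, blur-free fields: background is exactly 100 DN, anti-aliased
#   stroke tails sit below 150, every stroke peak exceeds 200
# - realistic fields (psf 0.15 um, shot + read noise): low = background +
#   half the blurred ridge amplitude (~250 DN) localises tips without bias
#   (half-maximum rule); high = background + 10 sd of the background noise
sim_cilia_seg_noisefree <- function()
  segmentation_config(hysteresis_params(150, 200, mode = "absolute"),
                      min_object_area_px = 5L, split_min_distance_px = 10L)
sim_nuclei_seg_noisefree <- function()
  segmentation_config(hysteresis_params(150, 200, mode = "absolute"),
                      min_object_area_px = 200L, split_min_distance_px = 15L)
sim_cilia_seg_noisy <- function()
  segmentation_config(hysteresis_params(225, 250, mode = "absolute"),
                      min_object_area_px = 5L, split_min_distance_px = 10L)
sim_nuclei_seg_noisy <- function()
  segmentation_config(hysteresis_params(200, 300, mode = "absolute"),
                      min_object_area_px = 200L, split_min_distance_px = 15L)

# match measured objects to simulated cilia by distance between the measured
# centroid and the path midpoint; returns data.frame(true, measured)
match_lengths <- function(meas, truth, pixel_size_um, max_dist_px = 10) {
  out <- list()
  for (k in seq_along(truth$paths)) {
    p <- truth$paths[[k]]
    mid <- p[ceiling(nrow(p) / 2), ] / pixel_size_um + 0.5
    if (nrow(meas) == 0) next
    d <- sqrt((meas$centroid_x - mid[1])^2 + (meas$centroid_y - mid[2])^2)
    j <- which.min(d)
    if (d[j] > max_dist_px) next
    out[[length(out) + 1L]] <- data.frame(
      true = truth$cilia$true_length_um[k], measured = meas$length_um[j])
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(true = numeric(), measured = numeric())
}
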