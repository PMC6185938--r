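#' Skeleton path length of a single object
#'
#' Thins the object to a 1-pixel-wide, 8-connected skeleton (Guo-Hall
#' thinning) and returns the longest geodesic path along it, counting 1 pixel
#' per axial step and sqrt(2) per diagonal step, scaled to micrometres. This
#' is the default length estimate for curvilinear structures such as cilia; a
#' single-pixel skeleton has length 0. No endpoint correction is applied.
#'
#' @param object_mask integer/logical `[y, x]` matrix with exactly one
#'   8-connected foreground component.
#' @param pixel_size_um pixel size in um/pixel.
#' @return Length in micrometres.
#' @examples
#' m <- matrix(0, 5, 15); m[3, 3:13] <- 1   # 1 x 11 px segment
#' skeleton_length(m, 0.1)                   # 10 steps * 0.1 = 1 um
#' @export
skeleton_length <- function(object_mask, pixel_size_um) {
  m <- as_binary(object_mask)
  if (!any(m != 0L)) stop("empty object mask")
  lab <- .cc_label8(m)
  if (max(lab) > 1L)
    stop("object mask has ", max(lab), " components; expected exactly one")
  skel <- .thin_guo_hall(m)
  .geodesic_diameter(skel) * pixel_size_um
}

# MATLAB-regionprops-style ellipse-equivalent axis from normalised second
# central moments (with the 1/12 per-pixel correction).
major_axis_px <- function(ys, xs) {
  n <- length(ys)
  my <- mean(ys); mx <- mean(xs)
  uyy <- sum((ys - my)^2) / n + 1 / 12
  uxx <- sum((xs - mx)^2) / n + 1 / 12
  uxy <- sum((ys - my) * (xs - mx)) / n
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  2 * sqrt(2) * sqrt(uxx + uyy + common)
}

#' Measure every labelled object
#'
#' Per-object morphometry in the spirit of `regionprops`: pixel area,
#' physical area, skeleton path length, ellipse-equivalent major axis
#' (an alternative length reading), mean intensity over the object's pixels
#' on the original (pre-threshold) intensity image, and centroid. Coordinates
#' are 1-based `(y, x)`, origin top-left.
#'
#' @param labels integer label matrix (`0` = background).
#' @param intensity numeric matrix of the same shape; the source image.
#' @param pixel_size_um pixel size in um/pixel.
#' @return A data frame with one row per label: `label`, `area_px`,
#'   `area_um2`, `length_um`, `major_axis_um`, `mean_intensity`,
#'   `centroid_y`, `centroid_x`. Empty label map gives a zero-row frame.
#' @export
measure_objects <- function(labels, intensity, pixel_size_um) {
  if (!is.matrix(labels) || !is.matrix(intensity))
    stop("`labels` and `intensity` must be matrices")
  if (!all(dim(labels) == dim(intensity)))
    stop("`labels` and `intensity` have different shapes")
  n <- max(labels)
  empty <- data.frame(label = integer(), area_px = integer(),
                      area_um2 = numeric(), length_um = numeric(),
                      major_axis_um = numeric(), mean_intensity = numeric(),
                      centroid_y = numeric(), centroid_x = numeric())
  if (n == 0L) return(empty)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  ys <- (idx - 1L) %% nrow(labels) + 1L
  xs <- (idx - 1L) %/% nrow(labels) + 1L
  ints <- intensity[idx]
  area <- tabulate(lab, nbins = n)
  mean_int <- as.numeric(rowsum(ints, lab)) / area
  cy <- as.numeric(rowsum(as.numeric(ys), lab)) / area
  cx <- as.numeric(rowsum(as.numeric(xs), lab)) / area
  len <- numeric(n)
  maj <- numeric(n)
  for (i in seq_len(n)) {
    sel <- lab == i
    y <- ys[sel]; x <- xs[sel]
    # crop to bounding box before thinning
    sub <- matrix(0L, max(y) - min(y) + 1L, max(x) - min(x) + 1L)
    sub[cbind(y - min(y) + 1L, x - min(x) + 1L)] <- 1L
    skel <- .thin_guo_hall(sub)
    len[i] <- .geodesic_diameter(skel) * pixel_size_um
    maj[i] <- major_axis_px(y, x) * pixel_size_um
  }
  data.frame(label = seq_len(n), area_px = area,
             area_um2 = area * pixel_size_um^2, length_um = len,
             major_axis_um = maj, mean_intensity = mean_int,
             centroid_y = cy, centroid_x = cx)
}

#' Ciliation incidence
#'
#' Incidence (frequency of ciliated cells) = number of cilia divided by the
#' number of nuclei in the same region, times 100. With zero nuclei the
#' value is undefined and `NA` is returned; values above 100 are reported as
#' is (they flag multiciliation or over-segmentation, handled by
#' [summarize_field()]).
#'
#' @param n_cilia,n_nuclei non-negative counts.
#' @return Percentage (may be `NA`).
#' @examples
#' compute_incidence(30, 100)  # 30
#' @export
compute_incidence <- function(n_cilia, n_nuclei) {
  if (n_cilia < 0 || n_nuclei < 0) stop("counts must be non-negative")
  if (n_nuclei == 0) return(NA_real_)
  n_cilia / n_nuclei * 100
}

#' Summarise one field of view
#'
#' Collapses per-cilium measurements plus the nuclei count of the same field
#' into the field-level readouts: cilia count, nuclei count, mean cilium
#' length (the average length of all cilia in the image; `NA` when none),
#' and incidence percentage. QC flags: `no_nuclei` when the nuclei count is
#' zero, `multiciliation_or_oversegmentation` when incidence exceeds 100.
#'
#' @param measurements data frame from [measure_objects()] for the cilia
#'   channel (may have zero rows).
#' @param n_nuclei nuclei count of the same field.
#' @param image_id identifier echoed into the output.
#' @return One-row data frame: `image_id`, `n_cilia`, `n_nuclei`,
#'   `mean_length_um`, `incidence_pct`, `qc_flags` (semicolon-separated,
#'   empty when clean).
#' @export
summarize_field <- function(measurements, n_nuclei, image_id = NA_character_) {
  n_cilia <- nrow(measurements)
  incidence <- compute_incidence(n_cilia, n_nuclei)
  flags <- character()
  if (n_nuclei == 0) flags <- c(flags, "no_nuclei")
  if (!is.na(incidence) && incidence > 100)
    flags <- c(flags, "multiciliation_or_oversegmentation")
  data.frame(
    image_id = as.character(image_id),
    n_cilia = n_cilia,
    n_nuclei = as.integer(n_nuclei),
    mean_length_um = if (n_cilia > 0) mean(measurements$length_um) else NA_real_,
    incidence_pct = incidence,
    qc_flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE)
}
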