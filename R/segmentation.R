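#' Hysteresis threshold parameters
#'
#' Dual thresholds for hysteresis segmentation, either as absolute
#' intensities or as quantiles of the image's own intensity distribution.
#' Quantile mode is the default shipped configuration because absolute
#' intensities depend on acquisition settings; the resolved absolute values
#' are attached to every segmentation result for provenance.
#'
#' @param low lower threshold: intensity (mode `"absolute"`) or quantile in
#'   `[0, 1]` (mode `"quantile"`).
#' @param high upper threshold, same convention; must resolve to a value
#'   >= `low`.
#' @param mode `"quantile"` or `"absolute"`.
#' @return A `hysteresis_params` list.
#' @export
hysteresis_params <- function(low = 0.90, high = 0.99, mode = c("quantile",
                                                                "absolute")) {
  mode <- match.arg(mode)
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || is.na(low) || is.na(high))
    stop("`low` and `high` must be single numbers")
  if (mode == "quantile" && (low < 0 || low > 1 || high < 0 || high > 1))
    stop("quantile thresholds must lie in [0, 1]")
  if (low > high)
    stop("`low` must not exceed `high`")
  structure(list(low = low, high = high, mode = mode),
            class = "hysteresis_params")
}

#' Segmentation configuration for one channel
#'
#' @param hysteresis a [hysteresis_params()].
#' @param min_object_area_px components smaller than this many pixels are
#'   removed as noise (>= 1; 1 disables the filter).
#' @param split_min_distance_px minimum separation, in pixels, between
#'   distance-transform peaks used to seed watershed splitting (>= 1).
#' @param watershed_tolerance minimum depth, in distance-map units, by which
#'   a peak must rise above the saddle to its neighbour to found its own
#'   object; shallower peaks are merged. Guards thin or elongated objects
#'   (whose distance ridge carries many near-equal maxima) against
#'   over-splitting.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(hysteresis = hysteresis_params(),
                                min_object_area_px = 5L,
                                split_min_distance_px = 10L,
                                watershed_tolerance = 1) {
  stopifnot(inherits(hysteresis, "hysteresis_params"))
  min_object_area_px <- as.integer(min_object_area_px)
  split_min_distance_px <- as.integer(split_min_distance_px)
  if (is.na(min_object_area_px) || min_object_area_px < 1L)
    stop("`min_object_area_px` must be >= 1")
  if (is.na(split_min_distance_px) || split_min_distance_px < 1L)
    stop("`split_min_distance_px` must be >= 1")
  structure(list(hysteresis = hysteresis,
                 min_object_area_px = min_object_area_px,
                 split_min_distance_px = split_min_distance_px,
                 watershed_tolerance = watershed_tolerance),
            class = "segmentation_config")
}

#' Resolve hysteresis thresholds against an image
#'
#' Absolute-mode parameters pass through unchanged; quantile-mode parameters
#' are resolved to the empirical quantiles (type 7, the R default) of the
#' image's flattened intensity distribution.
#'
#' @param image numeric `[y, x]` matrix.
#' @param params a [hysteresis_params()].
#' @return Named numeric vector `c(low = , high = )`.
#' @examples
#' img <- matrix(1:100, 10, 10)
#' resolve_thresholds(img, hysteresis_params(40, 90, mode = "absolute"))
#' @export
resolve_thresholds <- function(image, params) {
  stopifnot(inherits(params, "hysteresis_params"))
  if (length(image) == 0L) stop("empty image")
  if (params$mode == "absolute") {
    out <- c(low = params$low, high = params$high)
  } else {
    q <- stats::quantile(as.numeric(image), probs = c(params$low, params$high),
                         names = FALSE, type = 7)
    out <- c(low = q[1L], high = q[2L])
  }
  if (out["low"] > out["high"])
    stop("resolved low threshold exceeds high threshold")
  out
}

#' Hysteresis dual-threshold segmentation
#'
#' Pixels strictly above `high` seed objects; any pixel strictly above `low`
#' that is 8-connected to a seed through pixels strictly above `low` is
#' appended. Isolated intermediate pixels with no seeded connection stay
#' background, which is what suppresses speckle noise relative to a simple
#' low-pass threshold. `hysteresis_segment(img, t, t)` equals a simple strict
#' threshold at `t`.
#'
#' @param image numeric `[y, x]` matrix.
#' @param low,high absolute thresholds, `low <= high`.
#' @return Integer `[y, x]` matrix of 0/1 (class `binary_mask` semantics).
#' @examples
#' img <- matrix(c(0, 60, 120, 60, 0), 1, 5)
#' hysteresis_segment(img, 50, 100)  # 0 1 1 1 0
#' @export
hysteresis_segment <- function(image, low, high) {
  if (low > high) stop("`low` must not exceed `high`")
  if (!is.matrix(image)) stop("`image` must be a matrix")
  storage.mode(image) <- "double"
  .hysteresis_fill(image, low, high)
}

#' Remove small objects from a binary mask
#'
#' Deletes every 8-connected foreground component with fewer than
#' `min_area_px` pixels; larger components are untouched. This is the
#' size-based noise filter applied after hysteresis segmentation.
#'
#' @param mask integer/logical `[y, x]` matrix; non-zero = foreground.
#' @param min_area_px minimum component size to keep, >= 1.
#' @return Integer 0/1 matrix of the same shape.
#' @export
remove_small_objects <- function(mask, min_area_px) {
  min_area_px <- as.integer(min_area_px)
  if (is.na(min_area_px) || min_area_px < 1L)
    stop("`min_area_px` must be >= 1")
  m <- as_binary(mask)
  if (min_area_px == 1L) return(m)
  lab <- .cc_label8(m)
  n <- max(lab)
  if (n == 0L) return(m)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- sizes >= min_area_px
  out <- m
  out[lab > 0L & !keep[pmax(lab, 1L)]] <- 0L
  out
}

as_binary <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  m
}

#' Split touching objects by distance-transform watershed
#'
#' Partitions the foreground of a binary mask into labelled objects: the
#' Euclidean distance transform of the mask is flooded (negated) from its
#' local maxima, restricted to the mask. Peaks closer than
#' `min_distance_px`, or rising less than `tolerance` above their saddle,
#' are merged, so a component with one dominant distance peak keeps a single
#' label while overlapping convex objects (e.g. two fused nuclei) are split.
#' Labels are renumbered 1..N in raster order of each object's first pixel,
#' so the result is deterministic.
#'
#' @param mask integer/logical `[y, x]` matrix; non-zero = foreground.
#' @param min_distance_px minimum peak separation in pixels (>= 1).
#' @param tolerance minimum peak height above the merging saddle.
#' @return Integer label matrix (`0` background, `1..N` objects).
#' @export
split_touching_objects <- function(mask, min_distance_px = 10L,
                                   tolerance = 1) {
  min_distance_px <- as.integer(min_distance_px)
  if (is.na(min_distance_px) || min_distance_px < 1L)
    stop("`min_distance_px` must be >= 1")
  m <- as_binary(mask)
  if (!any(m != 0L)) return(matrix(0L, nrow(m), ncol(m)))
  dm <- matrix(as.numeric(EBImage::distmap(m)), nrow(m), ncol(m))
  lab <- .ws_split(dm, m, tolerance, min_distance_px)
  relabel_consecutive(lab)
}

# Renumber labels to consecutive 1..N ordered by first occurrence in
# column-major raster order.
relabel_consecutive <- function(lab) {
  ids <- lab[lab > 0L]
  if (length(ids) == 0L) return(lab)
  first <- ids[!duplicated(ids)]
  out <- lab
  out[lab > 0L] <- match(ids, first)
  storage.mode(out) <- "integer"
  out
}

#' Segment one channel image into labelled objects
#'
#' The full per-channel chain: resolve thresholds, hysteresis segmentation,
#' size-based noise removal, watershed splitting. The resolved absolute
#' thresholds are attached as attribute `"thresholds"` for provenance.
#'
#' @param image numeric `[y, x]` matrix.
#' @param config a [segmentation_config()].
#' @return Integer label matrix with attribute `thresholds`.
#' @examples
#' img <- matrix(0, 32, 32); img[10:12, 5:25] <- 500
#' lab <- segment_channel(img, segmentation_config(
#'   hysteresis_params(50, 100, mode = "absolute")))
#' max(lab)  # 1 object
#' @export
segment_channel <- function(image, config) {
  stopifnot(inherits(config, "segmentation_config"))
  thr <- resolve_thresholds(image, config$hysteresis)
  mask <- hysteresis_segment(image, thr["low"], thr["high"])
  mask <- remove_small_objects(mask, config$min_object_area_px)
  lab <- split_touching_objects(mask, config$split_min_distance_px,
                                config$watershed_tolerance)
  attr(lab, "thresholds") <- thr
  lab
}
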