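#' Simulation configuration for synthetic micrographs
#'
#' Describes one imaging condition for the synthetic-field generator: a
#' two-channel field (cilium marker + nuclear stain) of ellipse nuclei with
#' curvilinear cilia attached near nucleus borders, rendered with Gaussian
#' point-spread blur, constant background, Poisson shot noise on expected
#' intensity and additive Gaussian read noise (the standard fluorescence
#' camera model), quantised to 16-bit digital numbers.
#'
#' Cilium arc lengths are drawn from a log-normal distribution parameterised
#' by its median (um) and geometric standard deviation, which keeps lengths
#' strictly positive and right-skewed as biological length data are. Each
#' nucleus carries a cilium with probability `ciliation_probability`
#' (Binomial attachment), so the true per-field incidence fluctuates around
#' `100 * ciliation_probability`.
#'
#' @param image_size_px `c(ny, nx)` field size in pixels.
#' @param pixel_size_um in-plane pixel size, um/pixel.
#' @param n_nuclei nuclei per field (placed without overlap by rejection
#'   sampling unless `nuclei_overlap = TRUE`).
#' @param ciliation_probability probability in `[0, 1]` that a nucleus
#'   carries a cilium.
#' @param length_median_um median of the cilium arc-length distribution, um.
#' @param length_gsd geometric standard deviation of arc length (>= 1).
#' @param curvature_max maximum per-step heading change, radians.
#' @param step_um arc-length of one polyline step, um.
#' @param nucleus_radius_um mean nucleus semi-major axis, um (10% uniform
#'   jitter; minor axis = `nucleus_aspect` times major).
#' @param nucleus_aspect minor/major axis ratio of nuclei.
#' @param cilium_intensity,nucleus_intensity,background_intensity expected
#'   signal amplitudes in digital numbers.
#' @param psf_sigma_um Gaussian blur sigma, um (0 disables blur).
#' @param read_noise_sd additive Gaussian read noise sd, digital numbers
#'   (0 disables).
#' @param shot_noise logical; Poisson noise on the expected intensity.
#' @param nuclei_overlap logical; allow partially fused nuclei (exercises
#'   watershed splitting).
#' @param seed integer master seed for the field.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(image_size_px = c(512L, 512L),
                              pixel_size_um = 0.1,
                              n_nuclei = 15L,
                              ciliation_probability = 0.7,
                              length_median_um = 3.5,
                              length_gsd = 1.25,
                              curvature_max = 0.15,
                              step_um = 0.05,
                              nucleus_radius_um = 3.0,
                              nucleus_aspect = 0.8,
                              cilium_intensity = 800,
                              nucleus_intensity = 500,
                              background_intensity = 100,
                              psf_sigma_um = 0.15,
                              read_noise_sd = 10,
                              shot_noise = TRUE,
                              nuclei_overlap = FALSE,
                              seed = NULL) {
  if (ciliation_probability < 0 || ciliation_probability > 1)
    stop("`ciliation_probability` must lie in [0, 1]")
  if (length_median_um <= 0) stop("`length_median_um` must be > 0")
  if (length_gsd < 1) stop("`length_gsd` must be >= 1")
  if (any(c(pixel_size_um, step_um, nucleus_radius_um) <= 0))
    stop("sizes must be positive")
  if (any(c(cilium_intensity, nucleus_intensity, background_intensity,
            psf_sigma_um, read_noise_sd, curvature_max) < 0))
    stop("intensities, noise and curvature must be >= 0")
  structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um, n_nuclei = as.integer(n_nuclei),
    ciliation_probability = ciliation_probability,
    length_median_um = length_median_um, length_gsd = length_gsd,
    curvature_max = curvature_max, step_um = step_um,
    nucleus_radius_um = nucleus_radius_um, nucleus_aspect = nucleus_aspect,
    cilium_intensity = cilium_intensity,
    nucleus_intensity = nucleus_intensity,
    background_intensity = background_intensity,
    psf_sigma_um = psf_sigma_um, read_noise_sd = read_noise_sd,
    shot_noise = shot_noise, nuclei_overlap = nuclei_overlap, seed = seed),
    class = "simulation_config")
}

#' Sample a curvilinear cilium centreline
#'
#' Builds a planar polyline from fixed-length steps whose heading performs a
#' bounded random walk: each step turns by an angle drawn uniformly from
#' `[-curvature_max, curvature_max]`. The total arc length is
#' `round(length_um / step_um) * step_um`, i.e. within half a step of the
#' target. Uses the current R random number generator state.
#'
#' @param length_um target arc length, um (> 0).
#' @param curvature_max maximum per-step turning angle, radians.
#' @param step_um step arc length, um (> 0).
#' @param start `c(x, y)` start point, um.
#' @param heading initial heading, radians.
#' @return An `(n_steps + 1) x 2` matrix of `(x, y)` vertices in um, with
#'   attribute `arc_length_um`.
#' @examples
#' set.seed(1)
#' p <- sample_cilium_path(4, curvature_max = 0, step_um = 0.05)
#' attr(p, "arc_length_um")                 # 4
#' sqrt(sum((p[nrow(p), ] - p[1, ])^2))     # straight: end-to-end = 4
#' @export
sample_cilium_path <- function(length_um, curvature_max = 0.15,
                               step_um = 0.05, start = c(0, 0), heading = 0) {
  if (length_um <= 0 || step_um <= 0)
    stop("`length_um` and `step_um` must be positive")
  n <- max(1L, as.integer(round(length_um / step_um)))
  turns <- if (curvature_max > 0)
    stats::runif(n, -curvature_max, curvature_max) else numeric(n)
  turns[1L] <- 0  # first step follows the initial heading
  headings <- heading + cumsum(turns)
  xs <- start[1L] + c(0, cumsum(step_um * cos(headings)))
  ys <- start[2L] + c(0, cumsum(step_um * sin(headings)))
  out <- cbind(x = xs, y = ys)
  attr(out, "arc_length_um") <- n * step_um
  out
}

# Max-splat an anti-aliased ~1-px-wide stroke of the polyline (um coords)
# into weight matrix W (values in [0,1]). Pixel (i,j) centre sits at
# ((j-0.5)*psz, (i-0.5)*psz) um. Returns updated W.
rasterize_polyline <- function(W, path_um, pixel_size_um) {
  ny <- nrow(W); nx <- ncol(W)
  # densify to ~0.25 px spacing
  seg <- diff(path_um)
  seg_len <- sqrt(rowSums(seg^2))
  pts <- list(path_um[1L, , drop = FALSE])
  spacing <- 0.25 * pixel_size_um
  for (i in seq_len(nrow(seg))) {
    k <- max(1L, ceiling(seg_len[i] / spacing))
    tt <- seq_len(k) / k
    pts[[i + 1L]] <- cbind(path_um[i, 1L] + tt * seg[i, 1L],
                           path_um[i, 2L] + tt * seg[i, 2L])
  }
  pts <- do.call(rbind, pts)
  # continuous pixel coordinates (1-based centres)
  cx <- pts[, 1L] / pixel_size_um + 0.5
  cy <- pts[, 2L] / pixel_size_um + 0.5
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0;  fy <- cy - y0
  for (d in 1:4) {
    xi <- x0 + (d == 2L | d == 4L)
    yi <- y0 + (d == 3L | d == 4L)
    w <- (if (d %in% c(2L, 4L)) fx else 1 - fx) *
         (if (d %in% c(3L, 4L)) fy else 1 - fy)
    ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny & w > 0
    if (!any(ok)) next
    idx <- (xi[ok] - 1) * ny + yi[ok]
    # per-pixel maximum over splats keeps stroke amplitude constant
    agg <- tapply(w[ok], idx, max)
    ii <- as.integer(names(agg))
    W[ii] <- pmax(W[ii], as.numeric(agg))
  }
  W
}

# Ellipse radius along direction phi (relative to major axis at angle theta)
ellipse_radius <- function(a, b, theta, phi) {
  t <- phi - theta
  (a * b) / sqrt((b * cos(t))^2 + (a * sin(t))^2)
}

#' Render one synthetic two-channel field with ground truth
#'
#' Draws nuclei positions and shapes, attaches cilia (Binomial per nucleus)
#' anchored just outside nucleus borders and heading outward, rasterises
#' both channels, then applies blur, background and noise per the
#' configuration. Cilia are rejected and re-drawn if they would leave the
#' field or touch a previously placed cilium, so objects are non-touching by
#' construction; nuclei are non-overlapping unless `nuclei_overlap`.
#'
#' All randomness flows from `seed`; identical configurations and seed give
#' identical images and ground truth.
#'
#' @param config a [simulation_config()].
#' @param seed optional integer overriding `config$seed`.
#' @param image_id identifier stored in the ground truth.
#' @return A list: `stack` (an [image_stack()] with channels
#'   `c("ARL13B", "DAPI")`), `truth` with `cilia` (per-cilium data frame:
#'   `image_id`, `cilium_id`, `nucleus_id`, `true_length_um`), `field`
#'   (one-row data frame: `image_id`, `n_nuclei`, `n_cilia`,
#'   `incidence_pct`) and `paths` (list of vertex matrices in um).
#' @examples
#' \donttest{
#' f <- render_field(simulation_config(image_size_px = c(256, 256),
#'                                     n_nuclei = 6, seed = 7))
#' f$truth$field
#' }
#' @export
render_field <- function(config, seed = NULL, image_id = "field_1") {
  stopifnot(inherits(config, "simulation_config"))
  seed <- if (!is.null(seed)) seed else config$seed
  if (is.null(seed)) stop("a seed is required (config$seed or `seed`)")
  set.seed(as.integer(seed))
  ny <- config$image_size_px[1L]
  nx <- config$image_size_px[2L]
  psz <- config$pixel_size_um

  # ---- nuclei placement (rejection sampling) ----
  n <- config$n_nuclei
  a <- config$nucleus_radius_um * stats::runif(n, 0.9, 1.1) / psz  # px
  b <- a * config$nucleus_aspect
  theta <- stats::runif(n, 0, pi)
  min_gap <- if (config$nuclei_overlap) 0.75 else 1.05
  cxs <- numeric(n); cys <- numeric(n)
  attempts <- 0L
  if (any(a + 2 >= pmin(nx, ny) - a - 1))
    stop("field too small for the configured nucleus radius")
  for (i in seq_len(n)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > 400L * n)
        stop("field too small to place ", n, " nuclei without overlap")
      cx <- stats::runif(1, a[i] + 2, nx - a[i] - 1)
      cy <- stats::runif(1, a[i] + 2, ny - a[i] - 1)
      if (i == 1L) break
      j <- seq_len(i - 1L)
      if (all(sqrt((cxs[j] - cx)^2 + (cys[j] - cy)^2) >
              min_gap * (a[i] + a[j]))) break
    }
    cxs[i] <- cx; cys[i] <- cy
  }

  dapi <- matrix(0, ny, nx)
  for (i in seq_len(n)) {
    xr <- max(1L, floor(cxs[i] - a[i] - 1)):min(nx, ceiling(cxs[i] + a[i] + 1))
    yr <- max(1L, floor(cys[i] - a[i] - 1)):min(ny, ceiling(cys[i] + a[i] + 1))
    xx <- matrix(xr, length(yr), length(xr), byrow = TRUE) - cxs[i]
    yy <- matrix(yr, length(yr), length(xr)) - cys[i]
    u <- xx * cos(theta[i]) + yy * sin(theta[i])
    v <- -xx * sin(theta[i]) + yy * cos(theta[i])
    inside <- (u / a[i])^2 + (v / b[i])^2 <= 1
    sub <- dapi[yr, xr]
    sub[inside] <- pmax(sub[inside], config$nucleus_intensity)
    dapi[yr, xr] <- sub
  }

  # ---- cilia ----
  ciliated <- stats::rbinom(n, 1L, config$ciliation_probability) == 1L
  Wcil <- matrix(0, ny, nx)       # stroke weights
  occupied <- matrix(FALSE, ny, nx)
  cilia <- list()
  paths <- list()
  cid <- 0L
  for (i in which(ciliated)) {
    len <- stats::rlnorm(1, meanlog = log(config$length_median_um),
                         sdlog = log(config$length_gsd))
    placed <- FALSE
    for (try in 1:100) {
      phi <- stats::runif(1, 0, 2 * pi)
      r0 <- ellipse_radius(a[i], b[i], theta[i], phi) + 1.5  # px, just outside
      start_um <- c((cxs[i] + r0 * cos(phi) - 0.5) * psz,
                    (cys[i] + r0 * sin(phi) - 0.5) * psz)
      path <- sample_cilium_path(len, config$curvature_max, config$step_um,
                                 start = start_um, heading = phi)
      pxs <- path[, 1L] / psz + 0.5
      pys <- path[, 2L] / psz + 0.5
      if (any(pxs < 3 | pxs > nx - 2 | pys < 3 | pys > ny - 2)) next
      Wtry <- rasterize_polyline(matrix(0, ny, nx), path, psz)
      hit <- which(Wtry > 0.05)
      # reject if the new stroke comes within 1 px of an existing cilium
      ys0 <- (hit - 1L) %% ny + 1L
      xs0 <- (hit - 1L) %/% ny + 1L
      clash <- FALSE
      for (dy in -1:1) {
        for (dx in -1:1) {
          yy <- pmin(pmax(ys0 + dy, 1L), ny)
          xx <- pmin(pmax(xs0 + dx, 1L), nx)
          if (any(occupied[(xx - 1L) * ny + yy])) { clash <- TRUE; break }
        }
        if (clash) break
      }
      if (clash) next
      Wcil <- pmax(Wcil, Wtry)
      occupied[hit] <- TRUE
      cid <- cid + 1L
      cilia[[cid]] <- data.frame(
        image_id = image_id, cilium_id = cid, nucleus_id = i,
        true_length_um = attr(path, "arc_length_um"),
        stringsAsFactors = FALSE)
      paths[[cid]] <- path
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place a cilium without contact after 100 attempts; ",
           "field too crowded")
  }
  arl <- Wcil * config$cilium_intensity

  # ---- optics and camera ----
  degrade <- function(img) {
    if (config$psf_sigma_um > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = config$psf_sigma_um / psz))
    expected <- pmax(img + config$background_intensity, 0)
    out <- if (config$shot_noise)
      matrix(stats::rpois(length(expected), expected), ny, nx)
    else expected
    if (config$read_noise_sd > 0)
      out <- out + matrix(stats::rnorm(length(out), 0, config$read_noise_sd),
                          ny, nx)
    pmin(pmax(round(out), 0), 65535)
  }
  px <- array(0, dim = c(ny, nx, 2L, 1L))
  px[, , 1L, 1L] <- degrade(arl)
  px[, , 2L, 1L] <- degrade(dapi)
  stack <- image_stack(px, psz, c("ARL13B", "DAPI"),
                       source_id = paste0("simulated:", image_id))

  cilia_df <- if (cid > 0L) do.call(rbind, cilia) else
    data.frame(image_id = character(), cilium_id = integer(),
               nucleus_id = integer(), true_length_um = numeric(),
               stringsAsFactors = FALSE)
  field_df <- data.frame(
    image_id = image_id, n_nuclei = n, n_cilia = cid,
    incidence_pct = cid / n * 100, stringsAsFactors = FALSE)
  list(stack = stack,
       truth = list(cilia = cilia_df, field = field_df, paths = paths))
}

#' Simulate a multi-group imaging experiment to disk
#'
#' Renders `n_fields` fields for each named group configuration, writes them
#' as OME-TIFF files plus `truth_cilia.csv`, `truth_fields.csv` and an
#' echoed `sim_config.yaml` under `out_dir`, and returns the manifest. Field
#' seeds are derived deterministically from the master seed, so a rerun with
#' the same seed reproduces every output byte for byte.
#'
#' @param group_configs named list of [simulation_config()], one per group
#'   (e.g. `list(WT = ..., RP11 = ...)`).
#' @param n_fields fields per group.
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @return A list: `manifest` (data frame `path`, `group`, `sample`),
#'   `truth_cilia`, `truth_fields`, `dir`.
#' @export
simulate_experiment <- function(group_configs, n_fields, seed, out_dir) {
  if (length(group_configs) < 1L) stop("need at least one group")
  if (is.null(names(group_configs)) || any(!nzchar(names(group_configs))))
    stop("`group_configs` must be a named list")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(); t_cilia <- list(); t_fields <- list()
  k <- 0L
  for (g in seq_along(group_configs)) {
    gname <- names(group_configs)[g]
    for (f in seq_len(n_fields)) {
      k <- k + 1L
      field_seed <- (as.integer(seed) + 7919L * g + 104729L * f) %% 2147483629L
      image_id <- sprintf("%s_f%02d", gname, f)
      fld <- render_field(group_configs[[g]], seed = field_seed,
                          image_id = image_id)
      path <- file.path(out_dir, paste0(image_id, ".ome.tiff"))
      write_image(fld$stack, path)
      fld$truth$cilia$group <- rep(gname, nrow(fld$truth$cilia))
      fld$truth$field$group <- gname
      manifest[[k]] <- data.frame(path = path, group = gname, sample = gname,
                                  stringsAsFactors = FALSE)
      t_cilia[[k]] <- fld$truth$cilia
      t_fields[[k]] <- fld$truth$field
    }
  }
  truth_cilia <- do.call(rbind, t_cilia)
  truth_fields <- do.call(rbind, t_fields)
  manifest <- do.call(rbind, manifest)
  utils::write.csv(truth_cilia, file.path(out_dir, "truth_cilia.csv"),
                   row.names = FALSE)
  utils::write.csv(truth_fields, file.path(out_dir, "truth_fields.csv"),
                   row.names = FALSE)
  echo <- lapply(group_configs, function(cf) lapply(unclass(cf), function(v)
    if (is.null(v)) NA else v))
  yaml::write_yaml(list(seed = seed, n_fields = n_fields, groups = echo),
                   file.path(out_dir, "sim_config.yaml"))
  list(manifest = manifest, truth_cilia = truth_cilia,
       truth_fields = truth_fields, dir = out_dir)
}
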