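#' Default segmentation configuration for the cilia channel
#'
#' Quantile hysteresis thresholds (0.90, 0.99) with a 5-px noise floor and a
#' 10-px watershed peak separation; suited to thin, sparse, bright
#' structures at around 0.1 um/pixel.
#' @return A [segmentation_config()].
#' @export
cilia_defaults <- function() {
  segmentation_config(hysteresis_params(0.90, 0.99, mode = "quantile"),
                      min_object_area_px = 5L, split_min_distance_px = 10L)
}

#' Default segmentation configuration for the nuclei channel
#'
#' Same chain as the cilia channel but with a large minimum area (nuclei are
#' orders of magnitude bigger than noise specks) and a wider watershed peak
#' separation so a single nucleus's distance ridge is not split.
#' @return A [segmentation_config()].
#' @export
nuclei_defaults <- function() {
  segmentation_config(hysteresis_params(0.90, 0.99, mode = "quantile"),
                      min_object_area_px = 200L, split_min_distance_px = 15L)
}

#' Measure every image of a manifest
#'
#' For each manifest row the image is read, both channels are reduced by
#' maximum-intensity projection, segmented with their own configurations
#' (thresholds resolved per image, since acquisition intensity varies by
#' field), cilia are measured and the field is summarised. A failure on one
#' image is reported as a warning and the image is skipped; it does not void
#' the batch.
#'
#' @param manifest data frame with columns `path`, `group`, `sample`.
#' @param channels a [channel_map()].
#' @param cilia_config,nuclei_config per-channel [segmentation_config()].
#' @param pixel_size_override optional um/pixel forwarded to [read_image()].
#' @param out_dir optional directory; when given, writes `objects.csv`,
#'   `fields.csv` and `run_log.json`.
#' @return A list: `objects` (per-cilium rows with `image_id`, `group`,
#'   `sample` prepended), `fields` (per-image summaries), `log` (per-image
#'   resolved thresholds, counts and any errors).
#' @export
run_measure <- function(manifest, channels = channel_map(),
                        cilia_config = cilia_defaults(),
                        nuclei_config = nuclei_defaults(),
                        pixel_size_override = NULL, out_dir = NULL) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("manifest is empty")
  if (!all(c("path", "group", "sample") %in% names(manifest)))
    stop("manifest needs columns path, group, sample")
  objects <- list(); fields <- list(); log <- list()
  for (r in seq_len(nrow(manifest))) {
    path <- manifest$path[r]
    image_id <- sub("\\.(ome\\.)?tiff?$", "", basename(path),
                    ignore.case = TRUE)
    res <- tryCatch({
      stk <- read_image(path, channels, pixel_size_override)
      cil_img <- max_intensity_projection(stk, channels$cilia_channel)
      nuc_img <- max_intensity_projection(stk, channels$nuclei_channel)
      cil_lab <- segment_channel(cil_img, cilia_config)
      nuc_lab <- segment_channel(nuc_img, nuclei_config)
      meas <- measure_objects(cil_lab, cil_img, stk$pixel_size_um)
      fld <- summarize_field(meas, n_nuclei = max(nuc_lab),
                             image_id = image_id)
      fld$group <- manifest$group[r]
      fld$sample <- manifest$sample[r]
      obj <- if (nrow(meas) > 0L)
        cbind(data.frame(image_id = image_id, group = manifest$group[r],
                         sample = manifest$sample[r],
                         stringsAsFactors = FALSE), meas)
      else NULL
      list(objects = obj, field = fld,
           log = list(image_id = image_id, status = "ok",
                      cilia_thresholds = as.list(attr(cil_lab, "thresholds")),
                      nuclei_thresholds = as.list(attr(nuc_lab, "thresholds")),
                      n_cilia = fld$n_cilia, n_nuclei = fld$n_nuclei))
    }, error = function(e) {
      warning("skipping image '", path, "': ", conditionMessage(e),
              call. = FALSE)
      list(objects = NULL, field = NULL,
           log = list(image_id = image_id, status = "error",
                      message = conditionMessage(e)))
    })
    objects[[r]] <- res$objects
    fields[[r]] <- res$field
    log[[r]] <- res$log
  }
  objects <- do.call(rbind, objects[!vapply(objects, is.null, TRUE)])
  fields <- do.call(rbind, fields[!vapply(fields, is.null, TRUE)])
  if (is.null(objects))
    objects <- data.frame(image_id = character(), group = character(),
                          sample = character())
  out <- list(objects = objects, fields = fields, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(objects, file.path(out_dir, "objects.csv"),
                     row.names = FALSE)
    utils::write.csv(fields, file.path(out_dir, "fields.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(tool = "cilimetry",
           version = as.character(utils::packageVersion("cilimetry")),
           images = log),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = 10,
      pretty = TRUE)
  }
  out
}

#' Group-level statistics for a measured experiment
#'
#' Computes, for mean cilium length and for incidence, per-group summaries
#' (mean +/- SEM) and the control-referenced tests: one-way ANOVA plus
#' Dunnett's post hoc test versus `control`. The observational unit is the
#' field by default; `unit = "per_cilium"` pools individual cilium lengths
#' instead (incidence is always per-field). Sample-level QC flags (minimum
#' cilia, cells and fields) are attached per group.
#'
#' @param fields per-field data frame from [run_measure()] (columns `group`,
#'   `n_cilia`, `n_nuclei`, `mean_length_um`, `incidence_pct`).
#' @param control control group label.
#' @param objects per-object data frame from [run_measure()]; required for
#'   `unit = "per_cilium"`.
#' @param unit `"per_field"` or `"per_cilium"` for the length tests.
#' @param qc a [qc_thresholds()].
#' @param out_dir optional directory; writes `groups.csv` and `stats.json`.
#' @return A list: `unit`, `control`, `groups` (summary data frame with
#'   per-group QC flags), `length` and `incidence` (each a
#'   `comparison_result` from [dunnett_vs_control()]).
#' @export
run_stats <- function(fields, control, objects = NULL,
                      unit = c("per_field", "per_cilium"),
                      qc = qc_thresholds(), out_dir = NULL) {
  unit <- match.arg(unit)
  if (!control %in% fields$group)
    stop("control group '", control, "' absent from data")
  group_levels <- unique(fields$group)
  group_levels <- c(control, setdiff(group_levels, control))

  length_values <- if (unit == "per_cilium") {
    if (is.null(objects) || nrow(objects) == 0L)
      stop("`objects` required for unit = 'per_cilium'")
    split(objects$length_um, factor(objects$group, levels = group_levels))
  } else {
    v <- fields$mean_length_um
    split(v, factor(fields$group, levels = group_levels))
  }
  length_values <- lapply(length_values, function(x) x[!is.na(x)])
  incidence_values <- split(fields$incidence_pct,
                            factor(fields$group, levels = group_levels))
  incidence_values <- lapply(incidence_values, function(x) x[!is.na(x)])

  summaries <- list()
  for (g in group_levels) {
    fl <- fields[fields$group == g, ]
    flags <- qc_flags(list(n_cilia = sum(fl$n_cilia),
                           n_cells = sum(fl$n_nuclei),
                           n_fields = nrow(fl)), qc)
    sl <- group_summary(length_values[[g]], g)
    si <- group_summary(incidence_values[[g]], g)
    summaries[[g]] <- data.frame(
      group = g, n_fields = nrow(fl), n_cilia = sum(fl$n_cilia),
      n_nuclei = sum(fl$n_nuclei),
      length_n = sl$n, length_mean = sl$mean, length_sem = sl$sem,
      incidence_n = si$n, incidence_mean = si$mean, incidence_sem = si$sem,
      qc_flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
  }
  groups <- do.call(rbind, summaries)
  rownames(groups) <- NULL

  length_test <- dunnett_vs_control(length_values, control = control)
  incidence_test <- dunnett_vs_control(incidence_values, control = control)
  out <- list(unit = unit, control = control, groups = groups,
              length = length_test, incidence = incidence_test)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(groups, file.path(out_dir, "groups.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(out, function(x) if (inherits(x, "comparison_result"))
        unclass(x) else x),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = 10,
      pretty = TRUE, dataframe = "rows")
  }
  out
}

#' Read a pipeline run configuration from YAML
#'
#' Expected sections: `manifest` (path of a CSV with `path,group,sample`),
#' `channels` (`cilia`, `nuclei`), `segmentation` with `cilia:`/`nuclei:`
#' blocks (`mode`, `low`, `high`, `min_object_area_px`,
#' `split_min_distance_px`), `qc` thresholds, `control_group`, `unit`,
#' optional `pixel_size_um` override and `out_dir`. Missing entries fall
#' back to package defaults.
#'
#' @param path YAML file path.
#' @return A list with `manifest`, `channels`, `cilia_config`,
#'   `nuclei_config`, `qc`, `control_group`, `unit`, `pixel_size_um`,
#'   `out_dir`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  seg_block <- function(block, defaults) {
    if (is.null(block)) return(defaults)
    hp <- hysteresis_params(
      low = block$low %||% defaults$hysteresis$low,
      high = block$high %||% defaults$hysteresis$high,
      mode = block$mode %||% defaults$hysteresis$mode)
    segmentation_config(
      hp,
      min_object_area_px = block$min_object_area_px %||%
        defaults$min_object_area_px,
      split_min_distance_px = block$split_min_distance_px %||%
        defaults$split_min_distance_px)
  }
  manifest <- if (!is.null(cfg$manifest))
    utils::read.csv(cfg$manifest, stringsAsFactors = FALSE) else NULL
  qc <- if (is.null(cfg$qc)) qc_thresholds() else do.call(qc_thresholds, cfg$qc)
  list(
    manifest = manifest,
    channels = channel_map(cfg$channels$cilia %||% "ARL13B",
                           cfg$channels$nuclei %||% "DAPI"),
    cilia_config = seg_block(cfg$segmentation$cilia, cilia_defaults()),
    nuclei_config = seg_block(cfg$segmentation$nuclei, nuclei_defaults()),
    qc = qc,
    control_group = cfg$control_group,
    unit = cfg$unit %||% "per_field",
    pixel_size_um = cfg$pixel_size_um,
    out_dir = cfg$out_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
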