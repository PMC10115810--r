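#' Load a batch run configuration
#'
#' Reads a YAML or JSON configuration describing a batch: the spatial scale,
#' preprocessing radius, threshold method, per-channel stain class and
#' metric, matching/tile radii, seeds and input/output paths. Every
#' referenced input path must exist at launch. The full configuration is
#' serialized into the run manifest so any run is reconstructible.
#'
#' @param path YAML (.yml/.yaml) or JSON config file, or a ready-made list.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(path) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.ya?ml$", path)) {
           if (!requireNamespace("yaml", quietly = TRUE))
             stop("yaml package needed for YAML configs", call. = FALSE)
           yaml::read_yaml(path)
         } else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(scale_um_per_px = 0.5, preprocess_radius_px = 50,
                   threshold_method = "default_isodata",
                   match_radius_um = 5, tile_radius_um = 200,
                   min_area_um2 = 9, seed = 0L, out_dir = ".",
                   heatmaps = TRUE)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  if (is.null(cfg$inputs) || length(cfg$inputs) == 0L)
    stop("invalid config: no inputs", call. = FALSE)
  cfg$inputs <- lapply(cfg$inputs, function(inp) {
    if (is.character(inp)) inp <- list(path = inp)
    inp$stain_class <- inp$stain_class %||% "membrane"
    inp$metric <- inp$metric %||%
      if (inp$stain_class == "nuclear") "per_mm2" else "area_fraction"
    inp
  })
  for (inp in cfg$inputs) {
    if (!file.exists(inp$path))
      stop("invalid config: missing input ", inp$path, call. = FALSE)
    if (!is.null(inp$outline) && !file.exists(inp$outline))
      stop("invalid config: missing outline ", inp$outline, call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Run the configured pipeline over a batch of sections
#'
#' Per input section: read, rolling-ball subtract, auto-threshold, restrict
#' to the region outline, then compute the configured metric (area fraction
#' for membrane stains, nucleus detections per mm^2 for nuclear stains).
#' Writes one summary CSV row per section/channel, a QC montage, and a
#' manifest (config, seeds, input checksums). A failing section is logged
#' and skipped, never aborts the batch; the exit status reflects failures.
#'
#' @param config a `run_config` (or path / list accepted by [run_config()]).
#' @return list with `summary` (data.frame), `failures` (named character),
#'   `status` (0 = all sections processed), `out_dir`.
#' @export
run_batch <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); failures <- character(0)
  masks <- list(); outlines <- list()
  for (inp in cfg$inputs) {
    res <- tryCatch({
      img <- read_calibrated_image(inp$path,
                                   inp$scale_um_per_px %||% cfg$scale_um_per_px)
      pre <- rolling_ball_subtract(img, cfg$preprocess_radius_px)
      thr <- auto_threshold(pre$image, cfg$threshold_method)
      if (!is.null(inp$outline)) {
        outl <- read_outline_geojson(inp$outline)
        region <- rasterize_outline(outl, img)
      } else {
        outl <- NULL
        region <- binary_mask(matrix(TRUE, nrow(img$pixels), ncol(img$pixels)),
                              img$scale_um_per_px)
      }
      pts <- NULL
      if (identical(inp$stain_class, "nuclear")) {
        pts <- detect_nuclei(thr$mask, cfg$min_area_um2)
      }
      if (isTRUE(cfg$heatmaps) &&
          cfg$tile_radius_um / img$scale_um_per_px >= 1) {
        hm <- density_heatmap(thr$mask, region, cfg$tile_radius_um)
        v <- hm$values; v[is.na(v)] <- 0
        write_calibrated_image(
          calibrated_image(v, img$scale_um_per_px),
          file.path(cfg$out_dir, paste0(img$source_id, "_heatmap.tif")),
          bits = 32L)
      }
      row <- section_summary(thr$mask, region, points = pts,
                             section_id = img$source_id,
                             channel_label = img$channel_label,
                             region_label = if (is.null(outl)) "full_frame"
                                            else outl$label)
      row$threshold <- thr$result$threshold
      list(row = row, mask = thr$mask, outline = outl)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[inp$path] <- conditionMessage(res)
    } else {
      rows[[length(rows) + 1L]] <- res$row
      masks[[length(masks) + 1L]] <- res$mask
      outlines[[length(outlines) + 1L]] <- res$outline
    }
  }
  summary_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  write.csv(summary_df, file.path(cfg$out_dir, "summary.csv"),
            row.names = FALSE)
  if (length(masks)) {
    mont <- make_montage(masks, outlines, columns = min(3L, length(masks)))
    write_calibrated_image(mont, file.path(cfg$out_dir, "montage.tif"),
                           bits = 8L)
  }
  manifest <- list(
    config = unclass(cfg),
    checksums = as.list(tools::md5sum(vapply(cfg$inputs, `[[`, "", "path"))),
    failures = as.list(failures),
    timestamp_unused = NULL)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(summary = summary_df, failures = failures,
       status = if (length(failures)) 1L else 0L, out_dir = cfg$out_dir)
}
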