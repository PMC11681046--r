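# Batch pipeline mirroring the three program components: binarization,
# invasion quantification, and data consolidation. Failures are isolated
# per spheroid; a batch never aborts wholesale on one bad image.

#' Batch run configuration
#'
#' @param input Either a directory scanned for
#'   `<sampleID>_<timepoint>.tif/png` pairs, or a manifest CSV with
#'   columns `sample_id, day0_path, day2_path` (optional `group`).
#' @param output_dir Directory receiving all outputs.
#' @param pixel_size_um Physical pixel size in um.
#' @param binarize A [binarize_config].
#' @param directionality Compute PCA directionality per spheroid
#'   (default `TRUE`).
#' @param polar_export Write per-spheroid polar CSVs (default `TRUE`).
#' @param closing_radius_px Boundary-segmentation closing radius.
#' @param group_map Optional named vector sample_id -> group.
#' @param seed Integer seed recorded in the run log (the quantification
#'   itself is deterministic).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, output_dir, pixel_size_um,
                       binarize = binarize_config(),
                       directionality = TRUE, polar_export = TRUE,
                       closing_radius_px = 5, group_map = NULL,
                       seed = 1L) {
  check_pixel_size(pixel_size_um)
  stopifnot(inherits(binarize, "binarize_config"))
  structure(list(input = input, output_dir = output_dir,
                 pixel_size_um = pixel_size_um, binarize = binarize,
                 directionality = isTRUE(directionality),
                 polar_export = isTRUE(polar_export),
                 closing_radius_px = closing_radius_px,
                 group_map = group_map, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `input`, `output_dir`, `pixel_size_um`, `threshold`,
#' `contrast_percentiles`, `background_sigma_px`, `apply_circular_mask`,
#' `directionality`, `polar_export`, `closing_radius_px`, `seed`.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file values.
#' @return A [run_config].
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  ov <- list(...)
  y[names(ov)] <- ov
  bc <- binarize_config(
    threshold = y$threshold %||% 0.16,
    contrast_percentiles = y$contrast_percentiles %||% c(1, 99),
    background_sigma_px = y$background_sigma_px %||% 0,
    apply_circular_mask = y$apply_circular_mask %||% TRUE)
  run_config(input = y$input, output_dir = y$output_dir,
             pixel_size_um = y$pixel_size_um, binarize = bc,
             directionality = y$directionality %||% TRUE,
             polar_export = y$polar_export %||% TRUE,
             closing_radius_px = y$closing_radius_px %||% 5,
             seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discover Day-0/Day-2 image pairs
#'
#' From a manifest CSV (`sample_id, day0_path, day2_path[, group]`) or
#' by scanning a directory for the `<sampleID>_<timepoint>.<ext>`
#' convention.
#'
#' @param input Manifest CSV path or directory.
#' @return data.frame with columns `sample_id, day0_path, day2_path,
#'   group`.
#' @export
discover_pairs <- function(input) {
  if (length(input) == 1L && dir.exists(input)) {
    files <- list.files(input, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[!grepl("_artifacts\\.", basename(files))]
    meta <- lapply(files, parse_image_filename)
    df <- data.frame(path = files,
                     id = vapply(meta, `[[`, "", "id"),
                     tp = vapply(meta, `[[`, "", "timepoint"))
    d0 <- df[grepl("^day\\s*0$", df$tp, ignore.case = TRUE), ]
    d2 <- df[grepl("^day\\s*[1-9][0-9]*$", df$tp, ignore.case = TRUE), ]
    ids <- sort(intersect(d0$id, d2$id))
    out <- data.frame(
      sample_id = ids,
      day0_path = d0$path[match(ids, d0$id)],
      day2_path = d2$path[match(ids, d2$id)],
      group = NA_character_)
    return(out)
  }
  if (!file.exists(input))
    stop("input manifest or directory not found: ", input, call. = FALSE)
  man <- utils::read.csv(input, stringsAsFactors = FALSE)
  need <- c("sample_id", "day0_path", "day2_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns sample_id, day0_path, day2_path",
         call. = FALSE)
  if (is.null(man$group)) man$group <- NA_character_
  man[order(man$sample_id), c(need, "group")]
}

log_line <- function(stage, id, status, detail = "") {
  message(sprintf("[%s] %s %s%s", stage, id, status,
                  if (nzchar(detail)) paste0(": ", detail) else ""))
}

find_artifact_mask <- function(image_path, pixel_size_um) {
  stem <- tools::file_path_sans_ext(image_path)
  for (ext in c(".tif", ".tiff", ".png")) {
    p <- paste0(stem, "_artifacts", ext)
    if (file.exists(p)) return(load_mask(p, pixel_size_um))
  }
  NULL
}

#' Batch binarization (program component 1)
#'
#' Binarizes every Day-0/Day-2 image of every pair with the configured
#' pipeline, auto-discovering `<stem>_artifacts.<ext>` masks, and writes
#' audit masks `<sampleID>_<timepoint>_mask.tif` (8-bit 0/255) into the
#' output directory.
#'
#' @param config A [run_config].
#' @return data.frame of per-image statuses (`ok` logical, `error`
#'   message if any).
#' @export
run_binarize <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pairs <- discover_pairs(config$input)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  echo_config(config)
  res <- list()
  for (i in seq_len(nrow(pairs))) {
    for (col in c("day0_path", "day2_path")) {
      path <- pairs[[col]][i]
      id <- pairs$sample_id[i]
      st <- tryCatch({
        if (!file.exists(path)) stop("missing image: ", path)
        img <- load_image(path, config$pixel_size_um)
        am <- find_artifact_mask(path, config$pixel_size_um)
        m <- binarize_pipeline(img, config$binarize, artifact_mask = am)
        out <- file.path(config$output_dir,
                         paste0(img$id, "_", img$timepoint, "_mask.tif"))
        write_mask_tiff(m, out)
        log_line("binarize", basename(path), "ok")
        data.frame(sample_id = id, image = path, ok = TRUE, error = "")
      }, error = function(e) {
        log_line("binarize", basename(path), "FAILED", conditionMessage(e))
        data.frame(sample_id = id, image = path, ok = FALSE,
                   error = conditionMessage(e))
      })
      res[[length(res) + 1L]] <- st
    }
  }
  do.call(rbind, res)
}

#' Quantify one binarized spheroid pair
#'
#' The core single-spheroid analysis: segment the Day-0 boundary, align
#' it onto Day 2 by centroid overlap, locate the outer pixels, and
#' assemble invasion metrics plus (optionally) the PCA directionality.
#'
#' @param day0_mask,day2_mask The binarized pair.
#' @param directionality Compute the PCA directionality (needs >= 2
#'   outer pixels; skipped with `NULL` result otherwise).
#' @param closing_radius_px Boundary-segmentation closing radius.
#' @return List `metrics` (an `invasion_metrics`), `directionality`
#'   (`directionality_result` or NULL), `boundary`, `outer_pixels`.
#' @export
quantify_pair <- function(day0_mask, day2_mask, directionality = TRUE,
                          closing_radius_px = 5) {
  boundary <- segment_boundary(day0_mask,
                               closing_radius_px = closing_radius_px)
  boundary <- align_boundary(boundary, day2_mask)
  ops <- find_outer_pixels(day2_mask, boundary)
  metrics <- summarize_invasion(day0_mask, day2_mask, boundary, ops)
  dir_res <- NULL
  if (directionality && nrow(ops$points) >= 2L)
    dir_res <- analyze_directionality(ops)
  list(metrics = metrics, directionality = dir_res, boundary = boundary,
       outer_pixels = ops)
}

#' Batch invasion quantification (program component 2)
#'
#' Loads the binarized masks written by [run_binarize] (or any masks
#' following the same naming), quantifies every pair with
#' [quantify_pair], and writes per-spheroid JSON, boundary exports and
#' polar CSVs. Per-spheroid failures are recorded and do not stop the
#' batch.
#'
#' @param config A [run_config].
#' @param mask_dir Directory holding `<sampleID>_<timepoint>_mask.tif`
#'   files; defaults to the output directory.
#' @return data.frame of per-spheroid statuses.
#' @export
run_quantify <- function(config, mask_dir = config$output_dir) {
  stopifnot(inherits(config, "run_config"))
  pairs <- discover_pairs(config$input)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  for (i in seq_len(nrow(pairs))) {
    id <- pairs$sample_id[i]
    st <- tryCatch({
      m0p <- file.path(mask_dir, paste0(id, "_Day0_mask.tif"))
      m2p <- mask_path_day2(mask_dir, id)
      if (!file.exists(m0p)) stop("missing Day-0 mask: ", m0p)
      m0 <- load_mask(m0p, config$pixel_size_um, id = id,
                      timepoint = "Day0")
      m2 <- load_mask(m2p, config$pixel_size_um, id = id,
                      timepoint = "Day2")
      q <- quantify_pair(m0, m2, directionality = config$directionality,
                         closing_radius_px = config$closing_radius_px)
      grp <- if (!is.null(config$group_map)) config$group_map[[id]]
             else pairs$group[i]
      write_spheroid_json(q$metrics,
                          file.path(config$output_dir,
                                    paste0(id, "_metrics.json")),
                          directionality = q$directionality,
                          group = if (is.null(grp)) NA_character_ else grp)
      export_boundary(q$boundary,
                      file.path(config$output_dir,
                                paste0(id, "_boundary.csv")))
      if (config$polar_export)
        export_polar_data(q$outer_pixels,
                          file.path(config$output_dir,
                                    paste0(id, "_polar.csv")))
      log_line("quantify", id, "ok",
               sprintf("%d outer px", q$metrics$n_outer_pixels))
      data.frame(sample_id = id, ok = TRUE, error = "")
    }, error = function(e) {
      log_line("quantify", id, "FAILED", conditionMessage(e))
      data.frame(sample_id = id, ok = FALSE, error = conditionMessage(e))
    })
    res[[length(res) + 1L]] <- st
  }
  do.call(rbind, res)
}

mask_path_day2 <- function(mask_dir, id) {
  cand <- list.files(mask_dir,
                     pattern = paste0("^", id, "_Day[1-9][0-9]*_mask\\.tif$"),
                     full.names = TRUE)
  if (length(cand) == 0L)
    stop("missing final-timepoint mask for ", id)
  sort(cand)[length(cand)]
}

#' Batch consolidation (program component 3)
#'
#' Gathers every `*_metrics.json` in the output directory into one
#' consolidated CSV with MAD outlier flags and a per-group summary.
#'
#' @param config A [run_config].
#' @return The `metric_table`.
#' @export
run_consolidate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  files <- sort(list.files(config$output_dir,
                           pattern = "_metrics\\.json$",
                           full.names = TRUE))
  tab <- consolidate(files, group_map = config$group_map,
                     csv_path = file.path(config$output_dir,
                                          "consolidated.csv"))
  log_line("consolidate", sprintf("%d spheroids", nrow(tab$rows)), "ok")
  tab
}

#' Full pipeline: binarize, quantify, consolidate
#'
#' @param config A [run_config].
#' @return List `binarize`, `quantify` (status data.frames) and `table`
#'   (the consolidated `metric_table`).
#' @export
run_all <- function(config) {
  b <- run_binarize(config)
  q <- run_quantify(config)
  tab <- run_consolidate(config)
  list(binarize = b, quantify = q, table = tab)
}

# Echo the effective configuration into the output directory so every
# run is self-describing.
echo_config <- function(config) {
  cfg <- list(input = config$input, output_dir = config$output_dir,
              pixel_size_um = config$pixel_size_um,
              threshold = config$binarize$threshold,
              contrast_percentiles = config$binarize$contrast_percentiles,
              background_sigma_px = config$binarize$background_sigma_px,
              apply_circular_mask = config$binarize$apply_circular_mask,
              directionality = config$directionality,
              polar_export = config$polar_export,
              closing_radius_px = config$closing_radius_px,
              seed = config$seed)
  yaml::write_yaml(cfg, file.path(config$output_dir, "run_config.yaml"))
  invisible()
}
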