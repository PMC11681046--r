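# Image and table I/O with physical pixel-size calibration.
#
# Coordinate convention used throughout the package: x = column index,
# y = row index, both 0-based, pixel centers at integer coordinates,
# y increasing downward (standard image frame). All angle math inherits
# this frame.

#' Construct a calibrated grayscale image
#'
#' A `calibrated_image` is a 2D grayscale raster with intensities in
#' \[0, 1\] together with the physical edge length of one pixel in
#' micrometres and sample metadata.
#'
#' @param pixels Numeric matrix (rows = image rows, columns = image
#'   columns) with values in \[0, 1\].
#' @param pixel_size_um Positive scalar, physical pixel edge length in um.
#' @param id Sample / spheroid identifier.
#' @param timepoint Free-text timepoint label (e.g. `"Day0"`, `"Day2"`).
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_um, id = NA_character_,
                             timepoint = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
    stop("grayscale intensities must lie in [0, 1] and contain no NA",
         call. = FALSE)
  check_pixel_size(pixel_size_um)
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         id = as.character(id), timepoint = as.character(timepoint)),
    class = "calibrated_image")
}

#' Construct a binary mask
#'
#' @param pixels Logical matrix of foreground pixels.
#' @inheritParams calibrated_image
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size_um, id = NA_character_,
                        timepoint = NA_character_) {
  if (is.numeric(pixels)) {
    storage.mode(pixels) <- "logical"
  }
  if (!is.matrix(pixels) || !is.logical(pixels) || anyNA(pixels))
    stop("`pixels` must be a logical matrix without NA", call. = FALSE)
  check_pixel_size(pixel_size_um)
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         id = as.character(id), timepoint = as.character(timepoint)),
    class = "binary_mask")
}

check_pixel_size <- function(pixel_size_um) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  invisible(pixel_size_um)
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %s %s: %d x %d px, %.4g um/px\n",
              x$id, x$timepoint, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_um))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s %s: %d x %d px, %d foreground, %.4g um/px\n",
              x$id, x$timepoint, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels), x$pixel_size_um))
  invisible(x)
}

#' Load a grayscale microscopy image
#'
#' Reads an 8- or 16-bit single-channel TIFF or PNG and rescales
#' intensities to \[0, 1\] by the dtype maximum (255 or 65535), so one
#' global threshold is comparable across a batch. Multi-channel files
#' require an explicit `channel` index; there is no silent RGB-to-gray
#' conversion. Sample id and timepoint are parsed from the
#' `<sampleID>_<timepoint>.<ext>` filename convention when not supplied.
#'
#' If TIFF resolution tags are present and disagree with the supplied
#' calibration by more than 1%, a warning is emitted; the supplied value
#' is always the one used.
#'
#' @param path Path to a TIFF or PNG file.
#' @param pixel_size_um Physical pixel size in um (user calibration).
#' @param channel Optional 1-based channel index for multi-channel files.
#' @param id,timepoint Optional metadata overriding the filename parse.
#' @return A [calibrated_image].
#' @export
load_image <- function(path, pixel_size_um, channel = NULL,
                       id = NULL, timepoint = NULL) {
  check_pixel_size(pixel_size_um)
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  info <- NULL
  arr <- switch(ext,
    "tif" = , "tiff" = {
      a <- tiff::readTIFF(path, info = TRUE)
      info <- attributes(a)
      a
    },
    "png" = png::readPNG(path),
    stop("unsupported image format '.", ext, "' (use TIFF or PNG): ", path,
         call. = FALSE))
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (is.null(channel))
      stop(sprintf(
        "image has %d channels; supply `channel` to select one: %s",
        nch, path), call. = FALSE)
    if (channel < 1L || channel > nch)
      stop(sprintf("channel %d out of range (image has %d channels)",
                   channel, nch), call. = FALSE)
    arr <- arr[, , channel]
  }
  if (!is.matrix(arr))
    stop("expected a 2D grayscale image: ", path, call. = FALSE)
  arr <- matrix(as.numeric(arr), nrow(arr), ncol(arr))  # drop file attrs
  check_resolution_tags(info, pixel_size_um, path)
  meta <- parse_image_filename(path)
  calibrated_image(arr, pixel_size_um,
                   id = if (is.null(id)) meta$id else id,
                   timepoint = if (is.null(timepoint)) meta$timepoint
                               else timepoint)
}

# TIFF x/y resolution tags come in dots-per-unit; compare implied um/px
# against the user calibration (warn-only; tag dialects vary).
check_resolution_tags <- function(info, pixel_size_um, path) {
  if (is.null(info) || is.null(info$x.resolution)) return(invisible())
  unit <- if (is.null(info$resolution.unit)) "inch" else info$resolution.unit
  per_um <- switch(tolower(unit),
                   "inch" = info$x.resolution / 25400,
                   "cm"   = info$x.resolution / 1e4,
                   return(invisible()))
  if (!is.finite(per_um) || per_um <= 0) return(invisible())
  tag_um <- 1 / per_um
  if (abs(tag_um - pixel_size_um) / pixel_size_um > 0.01)
    warning(sprintf(
      "TIFF resolution tag implies %.4g um/px but config says %.4g um/px; using config (%s)",
      tag_um, pixel_size_um, basename(path)), call. = FALSE)
  invisible()
}

parse_image_filename <- function(path) {
  stem <- tools::file_path_sans_ext(basename(path))
  m <- regmatches(stem, regexec("^(.*)_([^_]+)$", stem))[[1]]
  if (length(m) == 3L) list(id = m[2], timepoint = m[3])
  else list(id = stem, timepoint = NA_character_)
}

#' Load a binary mask image
#'
#' Reads a TIFF/PNG and thresholds at 0.5 of the dtype range, yielding a
#' [binary_mask]. Used for binarized outputs and artifact masks.
#'
#' @inheritParams load_image
#' @export
load_mask <- function(path, pixel_size_um, channel = NULL,
                      id = NULL, timepoint = NULL) {
  img <- load_image(path, pixel_size_um, channel = channel,
                    id = id, timepoint = timepoint)
  binary_mask(img$pixels > 0.5, img$pixel_size_um, img$id, img$timepoint)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask A [binary_mask].
#' @param path Output path.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  ok <- try(tiff::writeTIFF(mask$pixels * 1, path, bits.per.sample = 8L),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write mask TIFF: ", path, call. = FALSE)
  invisible(path)
}

#' Maximum z-projection of an image stack
#'
#' Collapses a fluorescence z-stack into one image by taking the per-pixel
#' maximum over slices. All slices must share shape and pixel size.
#'
#' @param stack List of [calibrated_image] objects of identical shape.
#' @return A [calibrated_image] with the elementwise maximum.
#' @export
max_z_projection <- function(stack) {
  if (length(stack) < 1L) stop("stack must contain >= 1 slice", call. = FALSE)
  stopifnot(all(vapply(stack, inherits, logical(1), "calibrated_image")))
  d1 <- dim(stack[[1]]$pixels)
  ps <- stack[[1]]$pixel_size_um
  for (s in stack) {
    if (!identical(dim(s$pixels), d1))
      stop("slice shape mismatch in z-stack", call. = FALSE)
    if (s$pixel_size_um != ps)
      stop("slice pixel-size mismatch in z-stack", call. = FALSE)
  }
  proj <- Reduce(pmax, lapply(stack, `[[`, "pixels"))
  calibrated_image(proj, ps, id = stack[[1]]$id,
                   timepoint = stack[[1]]$timepoint)
}

#' Column schema of the consolidated per-spheroid metrics table
#' @export
metrics_csv_columns <- function() {
  c("sample_id", "group", "n_outer_pixels", "area_day0_mm2",
    "area_day2_mm2", "delta_area_mm2", "outer_area_mm2",
    "mean_distance_mm", "max_distance_mm", "I_r_mm4",
    "pca_angle_max_deg", "pca_angle_min_deg", "I_max_mm4", "I_min_mm4",
    "mean_dist_max_mm", "mean_dist_min_mm", "moment_fold_change",
    "distance_fold_change")
}

#' Write per-spheroid metric records to CSV
#'
#' One row per spheroid following the consolidated schema
#' ([metrics_csv_columns]). Numeric fields round-trip losslessly at
#' double precision.
#'
#' @param rows A data.frame, or a list of named lists/records.
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(rows, path) {
  df <- metrics_records_to_df(rows)
  ok <- try(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write metrics CSV: ", path, call. = FALSE)
  invisible(path)
}

#' Read a consolidated metrics CSV
#' @param path CSV path written by [write_metrics_csv].
#' @return data.frame with the schema columns.
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

metrics_records_to_df <- function(rows) {
  cols <- metrics_csv_columns()
  if (is.data.frame(rows)) {
    missing <- setdiff(cols, names(rows))
    for (m in missing) rows[[m]] <- NA
    return(rows[, cols, drop = FALSE])
  }
  if (length(rows) == 0L) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df$sample_id <- character(0); df$group <- character(0)
    return(df)
  }
  recs <- lapply(rows, function(r) {
    vals <- lapply(cols, function(cn) if (is.null(r[[cn]])) NA else r[[cn]])
    as.data.frame(setNames(vals, cols))
  })
  do.call(rbind, recs)
}
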