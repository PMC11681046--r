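# Batch post-processing: MAD-based outlier flagging across spheroids and
# consolidation of per-spheroid results into one table.

#' Flag outliers by scaled median absolute deviation
#'
#' A value is an outlier when it lies more than `k` scaled MADs
#' (`1.4826 * median(|v - median(v)|)`, the normal-consistent scaling)
#' from the median. When the scaled MAD is zero (over half the values
#' tied at the median), any value different from the median is flagged.
#' Non-finite values are always flagged.
#'
#' @param values Numeric vector with at least one finite value.
#' @param k Cut-off in scaled-MAD units; default 3.
#' @return Logical vector, `TRUE` = outlier.
#' @export
mad_outlier_filter <- function(values, k = 3) {
  if (length(values) == 0L)
    stop("cannot filter an empty vector", call. = FALSE)
  fin <- is.finite(values)
  if (!any(fin))
    stop("need at least one finite value", call. = FALSE)
  v <- values[fin]
  med <- stats::median(v)
  smad <- stats::mad(v, center = med, constant = 1.4826)
  out <- rep(TRUE, length(values))
  out[fin] <- if (smad == 0) v != med else abs(v - med) > k * smad
  out
}

#' Write one spheroid's results as JSON
#'
#' Serializes [summarize_invasion] output (and optionally the
#' directionality result) to the per-spheroid JSON consumed by
#' [consolidate].
#'
#' @param metrics An `invasion_metrics` object.
#' @param path Output JSON path.
#' @param directionality Optional `directionality_result`.
#' @param group Optional experimental group label.
#' @export
write_spheroid_json <- function(metrics, path, directionality = NULL,
                                group = NA_character_) {
  stopifnot(inherits(metrics, "invasion_metrics"))
  rec <- unclass(metrics)
  rec$group <- group
  if (!is.null(directionality)) {
    stopifnot(inherits(directionality, "directionality_result"))
    d <- unclass(directionality)
    rec$pca_angle_max_deg <- d$angle_max_deg
    rec$pca_angle_min_deg <- d$angle_min_deg
    rec$I_max_mm4 <- d$I_max_mm4
    rec$I_min_mm4 <- d$I_min_mm4
    rec$mean_dist_max_mm <- d$mean_dist_max_mm
    rec$mean_dist_min_mm <- d$mean_dist_min_mm
    rec$moment_fold_change <- d$moment_fold_change
    rec$distance_fold_change <- d$distance_fold_change
    rec$pca_isotropic <- d$isotropic
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

# Metrics eligible for per-group MAD outlier flagging.
outlier_metric_columns <- function() {
  c("n_outer_pixels", "area_day0_mm2", "area_day2_mm2", "delta_area_mm2",
    "outer_area_mm2", "mean_distance_mm", "max_distance_mm", "I_r_mm4",
    "I_max_mm4", "I_min_mm4", "mean_dist_max_mm", "mean_dist_min_mm",
    "moment_fold_change", "distance_fold_change")
}

#' Consolidate per-spheroid JSON files into one table
#'
#' Reads every per-spheroid JSON, assembles one row per spheroid (sorted
#' by sample id), applies [mad_outlier_filter] to each metric within
#' each experimental group, and optionally writes the consolidated CSV
#' plus a per-group summary. Outlier rows are retained in the table and
#' only excluded from the summary statistics.
#'
#' @param per_spheroid_files Character vector of JSON paths written by
#'   [write_spheroid_json].
#' @param group_map Optional named character vector mapping sample_id to
#'   group; overrides any group stored in the files.
#' @param k MAD cut-off passed to [mad_outlier_filter].
#' @param csv_path Optional output path for the consolidated CSV; a
#'   `<stem>_summary.csv` is written beside it.
#' @return An object of class `metric_table`: `rows` (data.frame) and
#'   `outlier_flags` (logical data.frame, same row order).
#' @export
consolidate <- function(per_spheroid_files, group_map = NULL, k = 3,
                        csv_path = NULL) {
  if (length(per_spheroid_files) == 0L)
    stop("no per-spheroid files given", call. = FALSE)
  recs <- lapply(per_spheroid_files, function(f) {
    r <- try(jsonlite::read_json(f, simplifyVector = TRUE), silent = TRUE)
    if (inherits(r, "try-error") || is.null(r$sample_id))
      stop("malformed per-spheroid file: ", f, call. = FALSE)
    r
  })
  ids <- vapply(recs, function(r) as.character(r$sample_id), character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id in consolidation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  cols <- metrics_csv_columns()
  rows <- do.call(rbind, lapply(recs, function(r) {
    vals <- lapply(cols, function(cn) {
      v <- r[[cn]]
      if (is.null(v) || length(v) != 1L) NA else v
    })
    as.data.frame(setNames(vals, cols))
  }))
  if (!is.null(group_map))
    rows$group <- unname(group_map[rows$sample_id])
  ord <- order(rows$sample_id)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  grp <- ifelse(is.na(rows$group), "", as.character(rows$group))
  mcols <- intersect(outlier_metric_columns(), names(rows))
  flags <- as.data.frame(setNames(
    lapply(mcols, function(cn) {
      fl <- rep(FALSE, nrow(rows))
      for (g in unique(grp)) {
        sel <- grp == g
        v <- rows[[cn]][sel]
        if (all(!is.finite(v))) next
        fl[sel] <- mad_outlier_filter(v, k = k)
      }
      fl
    }), mcols))
  tab <- structure(list(rows = rows, outlier_flags = flags, k = k),
                   class = "metric_table")
  if (!is.null(csv_path)) {
    write_metrics_csv(rows, csv_path)
    utils::write.csv(summarize_metric_table(tab),
                     paste0(tools::file_path_sans_ext(csv_path),
                            "_summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  tab
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("<metric_table> %d spheroids, %d groups, %d outlier flags (k = %g)\n",
              nrow(x$rows), length(unique(x$rows$group)),
              sum(as.matrix(x$outlier_flags)), x$k))
  invisible(x)
}

#' Per-group summary statistics excluding outliers
#'
#' @param tab A `metric_table` from [consolidate].
#' @return Long-format data.frame with columns `group`, `metric`, `n`,
#'   `n_outliers`, `mean`, `median`, `sd` (outlier-flagged values
#'   excluded from the statistics).
#' @export
summarize_metric_table <- function(tab) {
  stopifnot(inherits(tab, "metric_table"))
  rows <- tab$rows
  grp <- ifelse(is.na(rows$group), "", as.character(rows$group))
  out <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    for (cn in names(tab$outlier_flags)) {
      v <- rows[[cn]][sel]
      fl <- tab$outlier_flags[[cn]][sel]
      keep <- !fl & is.finite(v)
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = cn, n = sum(sel), n_outliers = sum(fl),
        mean = if (any(keep)) mean(v[keep]) else NA_real_,
        median = if (any(keep)) stats::median(v[keep]) else NA_real_,
        sd = if (sum(keep) > 1) stats::sd(v[keep]) else NA_real_)
    }
  }
  do.call(rbind, out)
}
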