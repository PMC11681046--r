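# Invasion metrics over the outer pixels: area change, per-pixel radial
# distances/angles past the Day-0 boundary, and the radial area moment
# of inertia. All metrics are pixel-based; no nucleus or cell objects
# are ever formed.

#' Locate outer pixels and their radial distances and angles
#'
#' Every Day-2 foreground pixel whose center lies outside the aligned
#' Day-0 boundary polygon is collected, with its radial distance `d`
#' (along the ray from the Day-0 centroid through the pixel, measured
#' from the last boundary crossing; see [ray_boundary_distance]) and its
#' angle about the centroid ([pixel_angle]). Distances are returned in
#' mm; the pixel area `dA = (pixel_size_um / 1000)^2` mm^2.
#'
#' @param day2_mask A [binary_mask] of the final timepoint.
#' @param boundary The aligned `spheroid_boundary`.
#' @return An object of class `outer_pixel_set` with fields `points`
#'   (n x 2, pixel coordinates), `distances_mm`, `angles_deg` in
#'   \[-180, 180), `dA_mm2`, `pixel_size_um`, `center_px` (boundary
#'   centroid), `fallback_flags`, `boundary_ref`.
#' @export
find_outer_pixels <- function(day2_mask, boundary) {
  stopifnot(inherits(day2_mask, "binary_mask"),
            inherits(boundary, "spheroid_boundary"))
  idx <- which(day2_mask$pixels, arr.ind = TRUE)
  x <- idx[, 2] - 1
  y <- idx[, 1] - 1
  if (length(x)) {
    outside <- !point_in_boundary(boundary, x, y)
    x <- x[outside]; y <- y[outside]
  }
  ps <- day2_mask$pixel_size_um
  if (length(x)) {
    ray <- ray_boundary_distance(boundary, x, y)
    d_mm <- ray$distance_px * ps / 1000
    ang <- pixel_angle(x, y, boundary$centroid)
    fb <- ray$fallback
  } else {
    d_mm <- numeric(0); ang <- numeric(0); fb <- logical(0)
  }
  structure(
    list(points = cbind(x = x, y = y), distances_mm = d_mm,
         angles_deg = ang, dA_mm2 = (ps / 1000)^2, pixel_size_um = ps,
         center_px = boundary$centroid, fallback_flags = fb,
         boundary_ref = boundary$source_id),
    class = "outer_pixel_set")
}

#' Construct an outer-pixel set directly from coordinates
#'
#' Low-level constructor used by the synthetic generator and by analyses
#' that start from an externally computed pixel cloud.
#'
#' @param points n x 2 matrix of `(x, y)` pixel coordinates.
#' @param distances_mm Radial distances in mm (default 0).
#' @param angles_deg Angles in degrees (default computed from
#'   `center_px` when given, else 0).
#' @param pixel_size_um Pixel size in um.
#' @param center_px Reference center `(x, y)` in pixel coordinates.
#' @export
outer_pixel_set <- function(points, pixel_size_um, distances_mm = NULL,
                            angles_deg = NULL, center_px = c(0, 0)) {
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  n <- nrow(points)
  check_pixel_size(pixel_size_um)
  if (is.null(distances_mm)) distances_mm <- numeric(n)
  if (is.null(angles_deg)) {
    # points coincident with the center get angle 0 (undefined direction)
    angles_deg <- numeric(n)
    off <- points[, 1] != center_px[1] | points[, 2] != center_px[2]
    if (any(off))
      angles_deg[off] <- pixel_angle(points[off, 1], points[off, 2],
                                     center_px)
  }
  stopifnot(length(distances_mm) == n, length(angles_deg) == n,
            all(distances_mm >= 0))
  structure(
    list(points = points, distances_mm = as.numeric(distances_mm),
         angles_deg = as.numeric(angles_deg),
         dA_mm2 = (pixel_size_um / 1000)^2,
         pixel_size_um = as.numeric(pixel_size_um),
         center_px = as.numeric(center_px),
         fallback_flags = logical(n), boundary_ref = NA_character_),
    class = "outer_pixel_set")
}

#' @export
print.outer_pixel_set <- function(x, ...) {
  cat(sprintf(
    "<outer_pixel_set> %d pixels past boundary '%s'; mean d = %.4g mm\n",
    nrow(x$points), x$boundary_ref,
    if (nrow(x$points)) mean(x$distances_mm) else 0))
  invisible(x)
}

#' Angle of a pixel about the spheroid centroid
#'
#' `atan2(y_p - y_0, x_p - x_0)` in the image frame (y down), in degrees
#' mapped to \[-180, 180). With y increasing downward this renders
#' clockwise-positive on screen, the polar-plot convention.
#'
#' @param x,y Pixel coordinates (vectorized).
#' @param centroid Reference `(x0, y0)`.
#' @return Angles in degrees in \[-180, 180).
#' @export
pixel_angle <- function(x, y, centroid) {
  dx <- x - centroid[1]; dy <- y - centroid[2]
  if (any(dx == 0 & dy == 0))
    stop("angle undefined: point coincides with the centroid",
         call. = FALSE)
  a <- atan2(dy, dx) * 180 / pi
  a[a >= 180] <- a[a >= 180] - 360
  a
}

#' Stained-area change between timepoints
#'
#' Areas are foreground pixel counts times the pixel area; the change is
#' `Area_Day2 - Area_Day0`. A negative change (net area loss) is
#' reported with a warning, not clamped.
#'
#' @param day0_mask,day2_mask [binary_mask] objects of identical shape
#'   and pixel size.
#' @return Named list `area_day0_mm2`, `area_day2_mm2`,
#'   `delta_area_mm2`.
#' @export
area_change <- function(day0_mask, day2_mask) {
  stopifnot(inherits(day0_mask, "binary_mask"),
            inherits(day2_mask, "binary_mask"))
  if (!identical(dim(day0_mask$pixels), dim(day2_mask$pixels)))
    stop("Day-0 and Day-2 masks differ in shape", call. = FALSE)
  if (day0_mask$pixel_size_um != day2_mask$pixel_size_um)
    stop("Day-0 and Day-2 masks differ in pixel size", call. = FALSE)
  dA <- (day0_mask$pixel_size_um / 1000)^2
  n0 <- sum(day0_mask$pixels)
  n2 <- sum(day2_mask$pixels)
  if (n2 < n0)
    warning(sprintf("negative area change (%.4g mm^2): Day-2 area below Day-0",
                    (n2 - n0) * dA), call. = FALSE)
  list(area_day0_mm2 = n0 * dA, area_day2_mm2 = n2 * dA,
       delta_area_mm2 = (n2 - n0) * dA)
}

#' Radial area moment of inertia of invasion
#'
#' `I_r = sum_i d_i^2 * dA` over the outer pixels, in mm^4: an
#' integrative invasiveness metric combining invaded area with distance,
#' weighting far-invading area quadratically. Zero for an empty set.
#'
#' @param ops An `outer_pixel_set`.
#' @return Scalar `I_r` in mm^4.
#' @export
radial_moment <- function(ops) {
  stopifnot(inherits(ops, "outer_pixel_set"))
  sum(ops$distances_mm^2) * ops$dA_mm2
}

#' Assemble per-spheroid invasion metrics
#'
#' @param day0_mask,day2_mask The binarized timepoint pair.
#' @param boundary The aligned `spheroid_boundary`.
#' @param ops The `outer_pixel_set` from [find_outer_pixels].
#' @return An object of class `invasion_metrics`: areas (mm^2), outer
#'   pixel count and area, mean/max radial distance (mm), `I_r` (mm^4),
#'   a `zero_invasion` flag, and the count of ray-fallback pixels.
#' @export
summarize_invasion <- function(day0_mask, day2_mask, boundary, ops) {
  stopifnot(inherits(ops, "outer_pixel_set"))
  ac <- area_change(day0_mask, day2_mask)
  n <- nrow(ops$points)
  structure(
    list(sample_id = day0_mask$id,
         area_day0_mm2 = ac$area_day0_mm2,
         area_day2_mm2 = ac$area_day2_mm2,
         delta_area_mm2 = ac$delta_area_mm2,
         n_outer_pixels = n,
         outer_area_mm2 = n * ops$dA_mm2,
         mean_distance_mm = if (n) mean(ops$distances_mm) else 0,
         max_distance_mm = if (n) max(ops$distances_mm) else 0,
         I_r_mm4 = radial_moment(ops),
         zero_invasion = n == 0L,
         n_ray_fallback = sum(ops$fallback_flags)),
    class = "invasion_metrics")
}

#' @export
print.invasion_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<invasion_metrics> %s: dA = %.4g mm^2, outer px = %d, ",
           "mean d = %.4g mm, I_r = %.4g mm^4\n"),
    x$sample_id, x$delta_area_mm2, x$n_outer_pixels, x$mean_distance_mm,
    x$I_r_mm4))
  invisible(x)
}

#' Export per-pixel polar-plot data
#'
#' Writes one row per outer pixel with columns
#' `x_px, y_px, distance_mm, angle_deg`; the boundary is the plot origin
#' (distance 0).
#'
#' @param ops An `outer_pixel_set`.
#' @param path Output CSV path.
#' @export
export_polar_data <- function(ops, path) {
  stopifnot(inherits(ops, "outer_pixel_set"))
  df <- data.frame(x_px = ops$points[, 1], y_px = ops$points[, 2],
                   distance_mm = ops$distances_mm,
                   angle_deg = ops$angles_deg)
  ok <- try(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write polar CSV: ", path, call. = FALSE)
  invisible(path)
}

#' Polar scatter of invasion distance versus angle
#'
#' Renders the per-pixel distance-versus-angle cloud as a polar scatter
#' with the boundary at the plot center, optionally annotated with the
#' principal invasion axes.
#'
#' @param ops An `outer_pixel_set`.
#' @param directionality Optional `directionality_result` whose principal
#'   axes are drawn.
#' @return A ggplot object.
#' @export
plot_polar <- function(ops, directionality = NULL) {
  stopifnot(inherits(ops, "outer_pixel_set"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_polar requires the ggplot2 package", call. = FALSE)
  df <- data.frame(angle_deg = ops$angles_deg,
                   distance_mm = ops$distances_mm)
  p <- ggplot2::ggplot(df,
         ggplot2::aes(x = .data$angle_deg, y = .data$distance_mm)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::coord_polar(theta = "x", start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 135, by = 45)) +
    ggplot2::labs(x = "angle (deg)", y = "distance from boundary (mm)")
  if (!is.null(directionality)) {
    r <- max(df$distance_mm, 0)
    ax <- data.frame(
      angle_deg = c(directionality$angle_max_deg,
                    directionality$angle_max_deg + 180,
                    directionality$angle_min_deg,
                    directionality$angle_min_deg + 180),
      axis = rep(c("max", "min"), each = 2), r = r)
    ax$angle_deg[ax$angle_deg >= 180] <- ax$angle_deg[ax$angle_deg >= 180] - 360
    p <- p + ggplot2::geom_segment(
      data = ax,
      ggplot2::aes(x = .data$angle_deg, xend = .data$angle_deg,
                   y = 0, yend = .data$r, colour = .data$axis))
  }
  p
}
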