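# Anisotropic invasion: directional second moments of the outer-pixel
# area about arbitrary axes, PCA principal angles, and fold changes
# between the maximum- and minimum-invasion directions.

#' Directional area moments about rotated axes
#'
#' Pixel coordinates relative to `center_px` are rotated into the frame
#' `(x', y')` whose x'-axis points along `axis_angle_deg`; the moments
#' are `I_xprime = sum(y'^2 dA)` (spread about the x'-axis) and
#' `I_yprime = sum(x'^2 dA)` (spread about the y'-axis, i.e. extent
#' *along* x'). Units mm^4.
#'
#' @param ops An `outer_pixel_set`.
#' @param axis_angle_deg Orientation of the x'-axis in degrees (image
#'   frame, y down).
#' @param center_px `(x, y)` center of the transform, pixel coordinates.
#' @return Named numeric `c(I_xprime, I_yprime)` in mm^4.
#' @export
directional_moments <- function(ops, axis_angle_deg,
                                center_px = ops$center_px) {
  stopifnot(inherits(ops, "outer_pixel_set"))
  tc <- transformed_coords_mm(ops, axis_angle_deg, center_px)
  c(I_xprime = sum(tc$yp^2) * ops$dA_mm2,
    I_yprime = sum(tc$xp^2) * ops$dA_mm2)
}

transformed_coords_mm <- function(ops, axis_angle_deg, center_px) {
  s <- ops$pixel_size_um / 1000
  dx <- (ops$points[, 1] - center_px[1]) * s
  dy <- (ops$points[, 2] - center_px[2]) * s
  phi <- axis_angle_deg * pi / 180
  list(xp = cos(phi) * dx + sin(phi) * dy,
       yp = -sin(phi) * dx + cos(phi) * dy)
}

#' Principal invasion angles by PCA
#'
#' The outer-pixel cloud is centered at its coordinate mean and the
#' eigenvectors of the 2x2 coordinate covariance give the directions of
#' maximum and minimum invasion. Angles are axis orientations reported
#' in \[-90, 90) (image frame, y down). Clouds whose eigenvalue ratio is
#' below `isotropy_ratio` are flagged isotropic; exactly degenerate
#' (equal-eigenvalue) clouds return angle 0 with the flag set.
#'
#' @param ops An `outer_pixel_set` with at least 2 pixels.
#' @param center Either `"pixel_mean"` (default; the PCA centering used
#'   for the polar plots) or `"day0_centroid"` to take second moments
#'   about the spheroid centroid instead.
#' @param isotropy_ratio Eigenvalue ratio below which the cloud is
#'   reported isotropic (default 1.05).
#' @return List `angle_max_deg`, `angle_min_deg`, `center_px`,
#'   `eigenvalues` (descending, mm^2), `isotropic`.
#' @export
pca_principal_angles <- function(ops, center = c("pixel_mean",
                                                 "day0_centroid"),
                                 isotropy_ratio = 1.05) {
  stopifnot(inherits(ops, "outer_pixel_set"))
  center <- match.arg(center)
  n <- nrow(ops$points)
  if (n < 2L)
    stop("PCA requires at least 2 outer pixels", call. = FALSE)
  s <- ops$pixel_size_um / 1000
  ctr <- if (center == "pixel_mean") colMeans(ops$points) else ops$center_px
  dx <- (ops$points[, 1] - ctr[1]) * s
  dy <- (ops$points[, 2] - ctr[2]) * s
  # second-moment matrix about the chosen center (covariance when the
  # center is the mean)
  m <- matrix(c(sum(dx * dx), sum(dx * dy), sum(dx * dy), sum(dy * dy)),
              2, 2) / n
  ev <- eigen(m, symmetric = TRUE)
  lam <- ev$values
  if (lam[1] <= 0)
    stop("degenerate outer-pixel cloud: all pixels at one point",
         call. = FALSE)
  if ((lam[1] - lam[2]) <= 1e-12 * lam[1]) {
    return(list(angle_max_deg = 0, angle_min_deg = -90,
                center_px = as.numeric(ctr), eigenvalues = lam,
                isotropic = TRUE))
  }
  a_max <- axis_angle_deg(ev$vectors[, 1])
  a_min <- axis_angle_deg(ev$vectors[, 2])
  iso <- lam[2] > 0 && (lam[1] / lam[2]) < isotropy_ratio
  list(angle_max_deg = a_max, angle_min_deg = a_min,
       center_px = as.numeric(ctr), eigenvalues = lam, isotropic = iso)
}

# Axis (not vector) orientation of a 2D direction, in [-90, 90).
axis_angle_deg <- function(v) {
  a <- atan2(v[2], v[1]) * 180 / pi
  a <- a %% 180
  if (a >= 90) a <- a - 180
  a
}

#' Full directionality analysis of an outer-pixel set
#'
#' Composes [pca_principal_angles] with [directional_moments] at the
#' principal angle about the PCA center: `I_max` is the moment
#' quantifying spread along the maximum-invasion axis
#' (`sum(x'^2 dA)` with x' along that axis), `I_min` the analogue along
#' the minimum axis; mean principal-direction distances are the mean
#' absolute transformed coordinates; fold changes are max/min ratios
#' (>= 1). A cloud with essentially zero spread across the maximum axis
#' is flagged `degenerate_spread` and yields infinite fold changes
#' rather than an error.
#'
#' @inheritParams pca_principal_angles
#' @return An object of class `directionality_result`.
#' @export
analyze_directionality <- function(ops, center = c("pixel_mean",
                                                   "day0_centroid"),
                                   isotropy_ratio = 1.05) {
  pca <- pca_principal_angles(ops, center, isotropy_ratio)
  tc <- transformed_coords_mm(ops, pca$angle_max_deg, pca$center_px)
  i_max <- sum(tc$xp^2) * ops$dA_mm2   # extent along the max axis
  i_min <- sum(tc$yp^2) * ops$dA_mm2   # extent along the min axis
  md_max <- mean(abs(tc$xp))
  md_min <- mean(abs(tc$yp))
  degenerate <- i_min <= 1e-12 * i_max
  structure(
    list(center_px = pca$center_px,
         angle_max_deg = pca$angle_max_deg,
         angle_min_deg = pca$angle_min_deg,
         I_max_mm4 = i_max, I_min_mm4 = i_min,
         mean_dist_max_mm = md_max, mean_dist_min_mm = md_min,
         moment_fold_change = if (degenerate) Inf else i_max / i_min,
         distance_fold_change = if (md_min <= 0) Inf else md_max / md_min,
         isotropic = pca$isotropic, degenerate_spread = degenerate),
    class = "directionality_result")
}

#' @export
print.directionality_result <- function(x, ...) {
  cat(sprintf(
    paste0("<directionality_result> angles (max/min) %.1f/%.1f deg; ",
           "I %.4g/%.4g mm^4 (%.2fx); mean dist %.4g/%.4g mm (%.2fx)%s\n"),
    x$angle_max_deg, x$angle_min_deg, x$I_max_mm4, x$I_min_mm4,
    x$moment_fold_change, x$mean_dist_max_mm, x$mean_dist_min_mm,
    x$distance_fold_change,
    if (x$isotropic) " [isotropic]" else ""))
  invisible(x)
}
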