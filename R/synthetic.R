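# Synthetic fixture generator: Day-0/Day-2 image pairs and pixel clouds
# with analytically known invasion metrics, so the whole pipeline is
# testable without any microscopy data.

#' Specify a synthetic spheroid fixture
#'
#' Defines a rasterized Day-0 spheroid plus an invasion pattern with
#' closed-form reference metrics. A pixel is foreground iff its center
#' satisfies the shape inequality, matching the pixel-center coordinate
#' convention used throughout.
#'
#' @param image_shape `(height, width)` in pixels.
#' @param pixel_size_um Pixel size in um (default 1).
#' @param spheroid List describing the Day-0 body: `type = "disk"`
#'   (fields `radius`), `"ellipse"` (`a`, `b`, `orientation_deg`) or
#'   `"polygon"` (`vertices`, n x 2); optional `center` (default image
#'   center).
#' @param invasion List describing Day-2 additions: `type = "none"`;
#'   `"annulus"` (`r1`; inner radius is the disk radius); `"scattered"`
#'   (`n`, `sigma_px` = std across the minor axis, `sigma_ratio` =
#'   major/minor std ratio, `orientation_deg`); or `"single_pixels"`
#'   (`r_px`, `theta_deg` vectors of polar positions).
#' @param seed Integer seed; identical specs generate identical
#'   fixtures.
#' @param id Sample identifier stamped on the generated images.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(image_shape = c(201, 201), pixel_size_um = 1,
                         spheroid = list(type = "disk", radius = 50),
                         invasion = list(type = "none"),
                         seed = 1L, id = "SYN01") {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1))
  check_pixel_size(pixel_size_um)
  if (is.null(spheroid$center))
    spheroid$center <- c((image_shape[2] - 1) / 2, (image_shape[1] - 1) / 2)
  if (identical(invasion$type, "annulus")) {
    r0 <- spheroid$radius
    if (is.null(r0) || invasion$r1 <= r0)
      stop("annulus invasion requires a disk spheroid and r1 > radius",
           call. = FALSE)
  }
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um, spheroid = spheroid,
                 invasion = invasion, seed = as.integer(seed), id = id),
            class = "fixture_spec")
}

pixel_grid <- function(shape) {
  h <- shape[1]; w <- shape[2]
  list(x = matrix(0:(w - 1), h, w, byrow = TRUE),
       y = matrix(0:(h - 1), h, w))
}

rasterize_spheroid <- function(sph, shape) {
  g <- pixel_grid(shape)
  dx <- g$x - sph$center[1]; dy <- g$y - sph$center[2]
  switch(sph$type,
    disk = dx^2 + dy^2 <= sph$radius^2,
    ellipse = {
      th <- (if (is.null(sph$orientation_deg)) 0
             else sph$orientation_deg) * pi / 180
      u <- cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      (u / sph$a)^2 + (v / sph$b)^2 <= 1
    },
    polygon = {
      m <- point_in_polygon(as.vector(g$x), as.vector(g$y),
                            sph$vertices[, 1], sph$vertices[, 2])
      matrix(m, shape[1], shape[2])
    },
    stop("unknown spheroid type: ", sph$type, call. = FALSE))
}

#' Generate a Day-0/Day-2 mask pair with known metrics
#'
#' Day-0 is the rasterized spheroid; Day-2 is its union with the
#' invasion pixels. The returned `truth` record carries closed-form
#' reference values where the geometry admits them (disk/annulus/
#' Gaussian cloud population values) alongside exact rasterized counts.
#'
#' @param spec A [fixture_spec].
#' @return List with [binary_mask] elements `day0`, `day2` and a `truth`
#'   list.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  shape <- spec$image_shape
  day0 <- rasterize_spheroid(spec$spheroid, shape)
  inv <- spec$invasion
  ctr <- spec$spheroid$center
  s <- spec$pixel_size_um / 1000
  dA <- s^2
  truth <- list(type = inv$type, center_px = ctr,
                pixel_size_um = spec$pixel_size_um)
  add <- NULL  # n x 2 integer pixel coords added on Day 2
  if (identical(inv$type, "none")) {
    truth$delta_area_mm2 <- 0
    truth$mean_distance_mm <- 0
    truth$I_r_mm4 <- 0
    truth$n_outer <- 0L
  } else if (identical(inv$type, "annulus")) {
    r0 <- spec$spheroid$radius; r1 <- inv$r1
    g <- pixel_grid(shape)
    rr <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2)
    sel <- rr > r0 & rr <= r1
    add <- cbind(g$x[sel], g$y[sel])
    w <- r1 - r0
    # continuum integrals over the annulus, distances measured from r0
    mean_d_px <- 2 * ((r1^3 - r0^3) / 3 - r0 * (r1^2 - r0^2) / 2) /
      (r1^2 - r0^2)
    i_r_px4 <- 2 * pi * (w^4 / 4 + r0 * w^3 / 3)
    truth$mean_distance_mm <- mean_d_px * s
    truth$I_r_mm4 <- i_r_px4 * s^4
    truth$max_distance_mm <- w * s
    truth$n_outer <- nrow(add)
    truth$delta_area_mm2 <- nrow(add) * dA
    truth$raster_tol <- 0.03  # O(perimeter/area) rasterization margin
  } else if (identical(inv$type, "single_pixels")) {
    px <- round(ctr[1] + inv$r_px * cos(inv$theta_deg * pi / 180))
    py <- round(ctr[2] + inv$r_px * sin(inv$theta_deg * pi / 180))
    add <- cbind(px, py)
    r0 <- spec$spheroid$radius
    truth$distances_mm <- pmax(sqrt((px - ctr[1])^2 + (py - ctr[2])^2) -
                                 r0, 0) * s
    truth$n_outer <- nrow(add)
    truth$delta_area_mm2 <- nrow(add) * dA
  } else if (identical(inv$type, "scattered")) {
    cloud <- withr::with_seed(spec$seed, {
      sample_gaussian_cloud(inv$n, inv$sigma_px * inv$sigma_ratio,
                            inv$sigma_px, inv$orientation_deg, ctr)
    })
    add <- unique(round(cloud))
    truth$angle_deg <- axis_angle_deg(
      c(cos(inv$orientation_deg * pi / 180),
        sin(inv$orientation_deg * pi / 180)))
    truth$moment_fold_change <- inv$sigma_ratio^2  # population value
    truth$n_outer <- NA_integer_  # grid snapping & overlap make n inexact
  } else {
    stop("unknown invasion type: ", inv$type, call. = FALSE)
  }
  day2 <- day0
  if (!is.null(add) && nrow(add)) {
    if (any(add[, 1] < 0 | add[, 1] >= shape[2] |
            add[, 2] < 0 | add[, 2] >= shape[1]))
      stop("invasion pixels fall outside the image frame", call. = FALSE)
    day2[cbind(add[, 2] + 1L, add[, 1] + 1L)] <- TRUE
  }
  list(day0 = binary_mask(day0, spec$pixel_size_um, spec$id, "Day0"),
       day2 = binary_mask(day2, spec$pixel_size_um, spec$id, "Day2"),
       truth = truth)
}

sample_gaussian_cloud <- function(n, sigma_major, sigma_minor,
                                  orientation_deg, center) {
  u <- stats::rnorm(n, 0, sigma_major)
  v <- stats::rnorm(n, 0, sigma_minor)
  th <- orientation_deg * pi / 180
  cbind(center[1] + cos(th) * u - sin(th) * v,
        center[2] + sin(th) * u + cos(th) * v)
}

#' Generate an anisotropic Gaussian outer-pixel cloud
#'
#' Draws `n` points from a 2D Gaussian with major-axis std
#' `sigma_ratio * sigma_px` along `orientation_deg` and minor-axis std
#' `sigma_px`, returned directly as an [outer_pixel_set] (continuous
#' coordinates). Population reference values: principal angle =
#' `orientation_deg` (as an axis), moment fold change = `sigma_ratio^2`.
#'
#' @param n Number of points.
#' @param sigma_px Minor-axis standard deviation in pixels.
#' @param sigma_ratio Major/minor std ratio (>= 1).
#' @param orientation_deg Major-axis orientation.
#' @param center `(x, y)` cloud center in pixel coordinates.
#' @param pixel_size_um Pixel size in um.
#' @param seed Integer seed.
#' @return List `ops` (an `outer_pixel_set`) and `truth`.
#' @export
generate_pixel_cloud <- function(n, sigma_px, sigma_ratio = 1,
                                 orientation_deg = 0,
                                 center = c(0, 0), pixel_size_um = 1,
                                 seed = 1L) {
  pts <- withr::with_seed(as.integer(seed), {
    sample_gaussian_cloud(n, sigma_px * sigma_ratio, sigma_px,
                          orientation_deg, center)
  })
  ops <- outer_pixel_set(pts, pixel_size_um,
                         distances_mm =
                           sqrt((pts[, 1] - center[1])^2 +
                                (pts[, 2] - center[2])^2) *
                           pixel_size_um / 1000,
                         center_px = center)
  truth <- list(
    angle_deg = axis_angle_deg(c(cos(orientation_deg * pi / 180),
                                 sin(orientation_deg * pi / 180))),
    moment_fold_change = sigma_ratio^2)
  list(ops = ops, truth = truth)
}

#' Grayscale variant of a mask fixture
#'
#' Renders foreground at `nucleus_intensity`, background at
#' `background_intensity`, adds seeded Gaussian noise and clips to
#' \[0, 1\] — an end-to-end exercise for the binarization pipeline.
#'
#' @param pair Output of [generate_pair].
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param nucleus_intensity,background_intensity Flat intensities with
#'   `0 <= background < nucleus <= 1`.
#' @param seed Integer seed for the noise.
#' @return List of [calibrated_image] elements `day0`, `day2` (truth
#'   carried over unchanged).
#' @export
grayscale_variant <- function(pair, noise_sd = 0, nucleus_intensity = 0.8,
                              background_intensity = 0, seed = 1L) {
  stopifnot(background_intensity >= 0,
            background_intensity < nucleus_intensity,
            nucleus_intensity <= 1)
  render <- function(mask, which_seed) {
    px <- ifelse(mask$pixels, nucleus_intensity, background_intensity)
    if (noise_sd > 0) {
      px <- px + withr::with_seed(which_seed, {
        matrix(stats::rnorm(length(px), 0, noise_sd), nrow(px), ncol(px))
      })
      px[px < 0] <- 0; px[px > 1] <- 1
    }
    calibrated_image(px, mask$pixel_size_um, mask$id, mask$timepoint)
  }
  list(day0 = render(pair$day0, as.integer(seed)),
       day2 = render(pair$day2, as.integer(seed) + 1L),
       truth = pair$truth)
}

#' Write a synthetic fixture pair to disk
#'
#' Writes `<id>_Day0.tif`, `<id>_Day2.tif` (grayscale if `noise_sd > 0`
#' or `grayscale = TRUE`, else 0/255 masks) and `<id>_truth.json` into
#' `dir`.
#'
#' @param spec A [fixture_spec].
#' @param dir Output directory (created if needed).
#' @param grayscale Write grayscale intensity images instead of binary
#'   masks.
#' @param noise_sd,nucleus_intensity,background_intensity Passed to
#'   [grayscale_variant] when grayscale output is requested.
#' @return Invisibly, the paths written.
#' @export
write_fixture_pair <- function(spec, dir, grayscale = FALSE,
                               noise_sd = 0, nucleus_intensity = 0.8,
                               background_intensity = 0) {
  pair <- generate_pair(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p0 <- file.path(dir, paste0(spec$id, "_Day0.tif"))
  p2 <- file.path(dir, paste0(spec$id, "_Day2.tif"))
  if (grayscale || noise_sd > 0) {
    gs <- grayscale_variant(pair, noise_sd, nucleus_intensity,
                            background_intensity, seed = spec$seed)
    tiff::writeTIFF(gs$day0$pixels, p0, bits.per.sample = 16L)
    tiff::writeTIFF(gs$day2$pixels, p2, bits.per.sample = 16L)
  } else {
    write_mask_tiff(pair$day0, p0)
    write_mask_tiff(pair$day2, p2)
  }
  pt <- file.path(dir, paste0(spec$id, "_truth.json"))
  jsonlite::write_json(pair$truth, pt, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(p0, p2, pt))
}
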