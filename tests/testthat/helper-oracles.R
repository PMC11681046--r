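# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive geometry with their own (slow, scalar)
# code so the package implementation is checked against a second route.

# Random simple non-convex polygon: star polygon with sorted vertex
# angles and random radii (always simple).
make_star_polygon <- function(n = 12, r_min = 20, r_max = 60,
                              center = c(0, 0), seed = 1) {
  withr::with_seed(seed, {
    ang <- sort(stats::runif(n, 0, 2 * pi))
    rad <- stats::runif(n, r_min, r_max)
    cbind(x = center[1] + rad * cos(ang),
          y = center[2] + rad * sin(ang))
  })
}

# Exhaustive segment-by-segment ray intersection: for each point, solve
# the 2x2 system per edge and keep the last crossing before the point.
oracle_ray_distance <- function(vertices, centroid, px, py) {
  n <- nrow(vertices)
  vapply(seq_along(px), function(k) {
    p <- c(px[k], py[k])
    dir <- p - centroid
    tp <- sqrt(sum(dir^2))
    u <- dir / tp
    tbest <- -Inf
    for (i in seq_len(n)) {
      a <- vertices[i, ]
      b <- vertices[if (i == n) 1 else i + 1, ]
      A <- cbind(u, a - b)
      if (abs(det(A)) < 1e-14) next
      ts <- solve(A, a - centroid)
      if (ts[2] >= -1e-9 && ts[2] <= 1 + 1e-9 &&
          ts[1] > 1e-9 && ts[1] <= tp + 1e-9 && ts[1] > tbest)
        tbest <- ts[1]
    }
    if (!is.finite(tbest)) return(NA_real_)
    tp - tbest
  }, numeric(1))
}

# Disk mask on the pixel-center grid, as a binary_mask.
disk_mask <- function(h, w, cx, cy, r, pixel_size_um = 1, id = "D",
                      timepoint = "Day0") {
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  binary_mask((xs - cx)^2 + (ys - cy)^2 <= r^2, pixel_size_um, id,
              timepoint)
}

# Lossless 90-degree clockwise raster rotation of a binary_mask.
rotate_mask_90 <- function(mask) {
  px <- t(mask$pixels)[, nrow(mask$pixels):1, drop = FALSE]
  binary_mask(px, mask$pixel_size_um, mask$id, mask$timepoint)
}

# Translate a mask by whole pixels (content clipped at the frame edge
# must be avoided by the caller).
translate_mask <- function(mask, dx, dy) {
  px <- mask$pixels
  h <- nrow(px); w <- ncol(px)
  out <- matrix(FALSE, h, w)
  src <- which(px, arr.ind = TRUE)
  r <- src[, 1] + dy
  c <- src[, 2] + dx
  stopifnot(all(r >= 1 & r <= h & c >= 1 & c <= w))
  out[cbind(r, c)] <- TRUE
  binary_mask(out, mask$pixel_size_um, mask$id, mask$timepoint)
}

# Grayscale pair with a radially graded annulus: invasion intensity
# falls linearly from i_in at the boundary to i_out at r1, so the
# global threshold directly sets how deep an invasion shell survives.
graded_annulus_images <- function(h = 161, w = 161, r0 = 50, r1 = 70,
                                  nucleus = 0.8, i_in = 0.5, i_out = 0.02,
                                  noise_sd = 0.02, seed = 11,
                                  pixel_size_um = 1) {
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  rr <- sqrt((xs - cx)^2 + (ys - cy)^2)
  core <- rr <= r0
  shell <- rr > r0 & rr <= r1
  d0 <- ifelse(core, nucleus, 0)
  frac <- pmin(pmax((rr - r0) / (r1 - r0), 0), 1)
  d2 <- d0
  d2[shell] <- i_in + (i_out - i_in) * frac[shell]
  withr::with_seed(seed, {
    d0 <- d0 + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
    d2 <- d2 + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
  })
  clip01 <- function(m) { m[m < 0] <- 0; m[m > 1] <- 1; m }
  list(day0 = calibrated_image(clip01(d0), pixel_size_um, "GRAD", "Day0"),
       day2 = calibrated_image(clip01(d2), pixel_size_um, "GRAD", "Day2"))
}

# Write a small synthetic batch (masks) plus manifest; returns manifest
# path. Used by the pipeline and determinism tests.
write_synthetic_batch <- function(dir, n_pairs = 3, seed = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("SYN%02d", seq_len(n_pairs))
  withr::with_seed(seed, {
    for (i in seq_len(n_pairs)) {
      spec <- fixture_spec(
        image_shape = c(141, 141), pixel_size_um = 2,
        spheroid = list(type = "disk", radius = 30 + 3 * i),
        invasion = list(type = "annulus", r1 = 45 + 3 * i),
        seed = seed + i, id = ids[i])
      write_fixture_pair(spec, dir, grayscale = TRUE, noise_sd = 0.02)
    }
  })
  man <- data.frame(sample_id = ids,
                    day0_path = file.path(dir, paste0(ids, "_Day0.tif")),
                    day2_path = file.path(dir, paste0(ids, "_Day2.tif")),
                    group = rep(c("A", "B"), length.out = n_pairs))
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE, quote = FALSE)
  mp
}
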