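test_that("directional moments match a per-pixel rotation oracle", {
  # symmetric cross: identity transform reproduces sum(y^2), sum(x^2)
  pts <- rbind(c(10, 0), c(-10, 0), c(0, 4), c(0, -4))
  ops <- outer_pixel_set(pts, 1, center_px = c(0, 0))
  dm <- directional_moments(ops, 0, center_px = c(0, 0))
  s <- 1e-3
  expect_equal(unname(dm["I_xprime"]), sum((pts[, 2] * s)^2) * s^2)
  expect_equal(unname(dm["I_yprime"]), sum((pts[, 1] * s)^2) * s^2)

  # single pixel at (10, 0): all moment along x
  one <- outer_pixel_set(cbind(10, 0), 1, center_px = c(0, 0))
  dm1 <- directional_moments(one, 0, center_px = c(0, 0))
  expect_equal(unname(dm1["I_yprime"]), 100 * s^4)
  expect_equal(unname(dm1["I_xprime"]), 0)

  # random cloud at an oblique axis vs brute-force rotate-then-sum
  pts <- withr::with_seed(12, matrix(stats::rnorm(1000, 0, 20), 500, 2))
  ops <- outer_pixel_set(pts, 2, center_px = c(0, 0))
  got <- directional_moments(ops, 37, center_px = c(1, -2))
  phi <- 37 * pi / 180
  sm <- 2e-3
  ix <- iy <- 0
  for (i in 1:500) {
    dx <- (pts[i, 1] - 1) * sm; dy <- (pts[i, 2] + 2) * sm
    xp <- cos(phi) * dx + sin(phi) * dy
    yp <- -sin(phi) * dx + cos(phi) * dy
    ix <- ix + yp^2 * sm^2
    iy <- iy + xp^2 * sm^2
  }
  expect_lt(abs(got["I_xprime"] / ix - 1), 1e-9)
  expect_lt(abs(got["I_yprime"] / iy - 1), 1e-9)

  empty <- outer_pixel_set(matrix(numeric(0), ncol = 2), 1)
  expect_equal(unname(directional_moments(empty, 10, c(0, 0))),
               c(0, 0))
})

test_that("PCA recovers axis-aligned and rotated ellipse orientations", {
  th <- seq(0, 2 * pi, length.out = 401)[-401]
  ell <- cbind(40 * cos(th), 10 * sin(th))
  ops <- outer_pixel_set(ell, 1, center_px = c(0, 0))
  pca <- pca_principal_angles(ops)
  expect_lt(abs(pca$angle_max_deg), 1)
  expect_equal(abs(pca$angle_max_deg - pca$angle_min_deg), 90,
               tolerance = 1e-6)

  phi <- 25 * pi / 180
  rot <- cbind(cos(phi) * ell[, 1] - sin(phi) * ell[, 2],
               sin(phi) * ell[, 1] + cos(phi) * ell[, 2])
  pca25 <- pca_principal_angles(outer_pixel_set(rot, 1))
  expect_lt(abs(pca25$angle_max_deg - 25), 1)

  ann <- cbind(55 * cos(th), 55 * sin(th))
  pann <- pca_principal_angles(outer_pixel_set(ann, 1))
  expect_true(pann$isotropic)
  expect_lt(pann$eigenvalues[1] / pann$eigenvalues[2], 1.05)

  expect_error(pca_principal_angles(outer_pixel_set(cbind(1, 1), 1)),
               "at least 2")
})

test_that("anisotropic Gaussian clouds give the population fold change", {
  cl <- generate_pixel_cloud(2000, sigma_px = 10, sigma_ratio = 3,
                             orientation_deg = 25, center = c(100, 100),
                             pixel_size_um = 1, seed = 7)
  res <- analyze_directionality(cl$ops)
  expect_lt(abs(res$angle_max_deg - cl$truth$angle_deg), 3)
  expect_lt(abs(res$moment_fold_change / cl$truth$moment_fold_change - 1),
            0.15)
  expect_gte(res$moment_fold_change, 1)
  expect_gte(res$distance_fold_change, 1)
  expect_gte(res$I_max_mm4, res$I_min_mm4)
  expect_equal(abs(res$angle_max_deg - res$angle_min_deg), 90,
               tolerance = 1e-6)
})

test_that("degenerate single-axis clouds are flagged, not errors", {
  line <- cbind(seq(-20, 20, by = 1), 0)
  res <- analyze_directionality(outer_pixel_set(line, 1))
  expect_true(res$degenerate_spread)
  expect_equal(res$I_min_mm4, 0)
  expect_equal(res$moment_fold_change, Inf)
})

test_that("directionality is rotation-equivariant", {
  cl <- generate_pixel_cloud(1500, sigma_px = 8, sigma_ratio = 2.5,
                             orientation_deg = 10, center = c(0, 0),
                             seed = 14)
  base <- analyze_directionality(cl$ops)
  for (phi_deg in c(30, 77)) {
    phi <- phi_deg * pi / 180
    p <- cl$ops$points
    rp <- cbind(cos(phi) * p[, 1] - sin(phi) * p[, 2],
                sin(phi) * p[, 1] + cos(phi) * p[, 2])
    res <- analyze_directionality(outer_pixel_set(rp, 1))
    dang <- (res$angle_max_deg - base$angle_max_deg - phi_deg) %% 180
    expect_lt(min(dang, 180 - dang), 1e-6)
    expect_lt(abs(res$I_max_mm4 / base$I_max_mm4 - 1), 1e-6)
    expect_lt(abs(res$I_min_mm4 / base$I_min_mm4 - 1), 1e-6)
    expect_lt(abs(res$moment_fold_change / base$moment_fold_change - 1),
              1e-6)
    # I_max + I_min is the rotation-invariant polar moment
    expect_lt(abs((res$I_max_mm4 + res$I_min_mm4) /
                  (base$I_max_mm4 + base$I_min_mm4) - 1), 1e-6)
  }
})

test_that("moment fold change equals the covariance eigenvalue ratio", {
  cl <- generate_pixel_cloud(800, sigma_px = 5, sigma_ratio = 2,
                             orientation_deg = -40, center = c(0, 0),
                             seed = 15)
  res <- analyze_directionality(cl$ops)
  pca <- pca_principal_angles(cl$ops)
  expect_lt(abs(res$moment_fold_change -
                pca$eigenvalues[1] / pca$eigenvalues[2]), 1e-9)
})
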