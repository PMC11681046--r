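test_that("mask centroid is the mean of foreground pixel centers", {
  m <- matrix(FALSE, 40, 40); m[21, 11] <- TRUE  # (x, y) = (10, 20)
  expect_equal(unname(mask_centroid(binary_mask(m, 1))), c(10, 20))

  m2 <- matrix(FALSE, 20, 20); m2[1, 1] <- TRUE; m2[1, 11] <- TRUE
  expect_equal(unname(mask_centroid(binary_mask(m2, 1))), c(5, 0))

  disk <- disk_mask(101, 121, 60, 40, 25)
  expect_lt(max(abs(mask_centroid(disk) - c(60, 40))), 0.1)

  expect_error(mask_centroid(binary_mask(matrix(FALSE, 5, 5), 1)), "empty")
})

test_that("boundary segmentation traces a disk at its radius", {
  disk <- disk_mask(121, 121, 60, 60, 50)
  b <- segment_boundary(disk)
  rr <- sqrt((b$vertices[, 1] - 60)^2 + (b$vertices[, 2] - 60)^2)
  expect_true(all(abs(rr - 50) <= 1))
  expect_lt(abs(boundary_area_px2(b) - pi * 50^2) / (pi * 50^2), 0.02)
  expect_lt(max(abs(b$centroid - c(60, 60))), 0.1)

  # interior hole is filled: boundary identical to the solid disk
  holed <- disk$pixels
  holed[59:63, 59:63] <- FALSE
  bh <- segment_boundary(binary_mask(holed, 1))
  expect_equal(bh$vertices, b$vertices)

  # a distant speck does not perturb the boundary (largest component)
  speck <- disk$pixels; speck[3, 3] <- TRUE
  bs <- segment_boundary(binary_mask(speck, 1))
  expect_equal(bs$vertices, b$vertices)

  expect_error(segment_boundary(binary_mask(matrix(FALSE, 9, 9), 1)),
               "empty")
  tiny <- matrix(FALSE, 30, 30); tiny[15, 15] <- TRUE
  expect_error(segment_boundary(binary_mask(tiny, 1), closing_radius_px = 0),
               "degenerate")
})

test_that("alignment is a pure translation from bulk centroids", {
  day0 <- disk_mask(141, 141, 60, 70, 35)
  b <- segment_boundary(day0)

  expect_equal(align_boundary(b, day0)$vertices, b$vertices)

  shifted <- translate_mask(day0, 7, -3)
  ba <- align_boundary(b, shifted)
  expect_equal(ba$vertices[, 1], b$vertices[, 1] + 7)
  expect_equal(ba$vertices[, 2], b$vertices[, 2] - 3)
  expect_equal(unname(ba$translation), c(7, -3))

  # scattered far pixels do not bias the bulk centroid
  noisy <- day0$pixels
  set <- withr::with_seed(9, cbind(sample(130:140, 50, TRUE),
                                   sample(1:141, 50, TRUE)))
  noisy[set] <- TRUE
  bn <- align_boundary(b, binary_mask(noisy, 1))
  expect_lt(sqrt(sum(bn$translation^2)), 0.5)

  expect_error(align_boundary(b, binary_mask(matrix(FALSE, 5, 5), 1)),
               "empty")
})

test_that("point-in-boundary matches an independent even-odd oracle", {
  skip_if_not_installed("pracma")
  poly <- make_star_polygon(n = 7, seed = 21)
  b <- spheroid_boundary(poly, 1)
  pts <- withr::with_seed(22, cbind(stats::runif(1000, -80, 80),
                                    stats::runif(1000, -80, 80)))
  got <- point_in_boundary(b, pts[, 1], pts[, 2])
  ref <- pracma::inpolygon(pts[, 1], pts[, 2], poly[, 1], poly[, 2],
                           boundary = TRUE)
  expect_identical(got, ref)

  expect_true(point_in_boundary(b, b$centroid[1], b$centroid[2]))
  far <- 2 * max(sqrt(rowSums(poly^2)))
  expect_false(point_in_boundary(b, far, far))
  # vertices themselves count as inside
  expect_true(all(point_in_boundary(b, poly[, 1], poly[, 2])))
})

test_that("ray distance matches analytic circle and brute-force oracles", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circle <- cbind(50 * cos(th), 50 * sin(th))
  b <- spheroid_boundary(circle, 1)
  r <- ray_boundary_distance(b, 80, 0)
  expect_lt(abs(r$distance_px - 30), 0.5)
  expect_lt(max(abs(r$hit - c(50, 0))), 0.5)
  expect_false(r$fallback)

  # point on the boundary -> zero distance
  r0 <- ray_boundary_distance(b, circle[10, 1], circle[10, 2])
  expect_equal(r0$distance_px, 0, tolerance = 1e-9)

  # star polygon with points beyond concavities, vs exhaustive oracle
  poly <- make_star_polygon(n = 11, r_min = 15, r_max = 60, seed = 31)
  bs <- spheroid_boundary(poly, 1)
  pts <- withr::with_seed(32, {
    ang <- stats::runif(300, 0, 2 * pi)
    rad <- stats::runif(300, 61, 120)
    cbind(rad * cos(ang), rad * sin(ang))
  })
  got <- ray_boundary_distance(bs, pts[, 1], pts[, 2])
  ref <- oracle_ray_distance(poly, bs$centroid, pts[, 1], pts[, 2])
  expect_true(all(!is.na(ref)))
  expect_lt(max(abs(got$distance_px - ref)), 1e-9)

  # the hit always lies between centroid and point: d <= |p - centroid|
  tp <- sqrt((pts[, 1] - bs$centroid[1])^2 + (pts[, 2] - bs$centroid[2])^2)
  expect_true(all(got$distance_px <= tp + 1e-9))
})

test_that("boundary segmentation is translation-equivariant", {
  day0 <- disk_mask(141, 141, 55, 60, 32)
  b1 <- segment_boundary(day0)
  b2 <- segment_boundary(translate_mask(day0, 9, 6))
  expect_equal(b2$vertices[, 1], b1$vertices[, 1] + 9)
  expect_equal(b2$vertices[, 2], b1$vertices[, 2] + 6)
  expect_equal(unname(b2$centroid - b1$centroid), c(9, 6))
})

test_that("boundary constructor validates the polygon", {
  expect_error(spheroid_boundary(rbind(c(0, 0), c(1, 0)), 1), "3 vertices")
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_error(spheroid_boundary(sq, 1, centroid = c(50, 50)), "inside")
  b <- spheroid_boundary(sq, 1)
  expect_equal(unname(b$centroid), c(5, 5))
})
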