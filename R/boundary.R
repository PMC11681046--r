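# Day-0 spheroid boundary: segmentation to a closed polygon, centroids,
# centroid-overlap alignment onto the Day-2 frame, and the ray geometry
# used for per-pixel radial distances.

#' Construct a spheroid boundary from polygon vertices
#'
#' Builds the invasion-reference polygon directly from coordinates, for
#' analytically defined boundaries. [segment_boundary] is the usual
#' entry point for image data.
#'
#' @param vertices n x 2 matrix of `(x, y)` vertices of a simple closed
#'   polygon (not repeated at the end), pixel coordinates.
#' @param pixel_size_um Pixel size in um.
#' @param centroid Optional `(x, y)`; defaults to the polygon area
#'   centroid. Must lie inside the polygon.
#' @param source_id Identifier of the originating sample.
#' @return An object of class `spheroid_boundary`.
#' @export
spheroid_boundary <- function(vertices, pixel_size_um, centroid = NULL,
                              source_id = NA_character_) {
  vertices <- matrix(as.numeric(vertices), ncol = 2,
                     dimnames = list(NULL, c("x", "y")))
  if (nrow(vertices) < 3L)
    stop("a boundary polygon needs at least 3 vertices", call. = FALSE)
  check_pixel_size(pixel_size_um)
  if (is.null(centroid)) centroid <- polygon_centroid(vertices)
  centroid <- as.numeric(centroid)
  if (!point_in_polygon(centroid[1], centroid[2], vertices[, 1],
                        vertices[, 2]))
    stop("centroid must lie inside the boundary polygon", call. = FALSE)
  structure(
    list(vertices = vertices, centroid = c(x = centroid[1], y = centroid[2]),
         alignment_centroid = c(x = centroid[1], y = centroid[2]),
         pixel_size_um = as.numeric(pixel_size_um),
         source_id = as.character(source_id),
         translation = c(x = 0, y = 0)),
    class = "spheroid_boundary")
}

#' Mask-pixel centroid
#'
#' Unweighted mean of foreground pixel-center coordinates.
#'
#' @param mask A [binary_mask] with at least one foreground pixel.
#' @return Numeric `(x, y)` in pixel coordinates.
#' @export
mask_centroid <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- which(mask$pixels, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("cannot compute centroid of an empty mask", call. = FALSE)
  c(x = mean(idx[, 2] - 1), y = mean(idx[, 1] - 1))
}

# 8-connected labelling built on EBImage's 4-connected bwlabel: merge
# label pairs that touch diagonally with a union-find pass.
label8 <- function(px) {
  lab <- EBImage::bwlabel(px * 1)
  lab <- matrix(as.integer(lab), nrow(px), ncol(px))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]    # down-left diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Largest 8-connected component of a logical matrix (ties broken by
# lowest label for determinism). Returns a logical matrix.
largest_component <- function(px) {
  lab <- label8(px)
  nl <- max(lab)
  if (nl == 0L) return(px & FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = nl)
  lab == which.max(sizes)
}

#' Segment the Day-0 spheroid boundary
#'
#' Produces the closed polygon used as the invasion reference:
#' morphological closing (disk radius `closing_radius_px`) bridges gaps
#' between stained nuclei, holes are filled, the largest 8-connected
#' component is kept, and its outer contour is traced at the 0.5
#' iso-level into an ordered polygon. The stored centroid is the area
#' centroid of that polygon; the mask-pixel centroid of the largest raw
#' component is retained separately for centroid-overlap alignment.
#'
#' @param day0_mask A [binary_mask] of the initial spheroid.
#' @param closing_radius_px Disk radius (pixels) of the morphological
#'   closing applied before contour tracing; default 5.
#' @param min_area_px Smallest acceptable component size; default 10.
#' @return An object of class `spheroid_boundary` with fields
#'   `vertices` (n x 2 matrix of `(x, y)`), `centroid`,
#'   `alignment_centroid`, `pixel_size_um`, `source_id`, `translation`.
#' @export
segment_boundary <- function(day0_mask, closing_radius_px = 5,
                             min_area_px = 10) {
  stopifnot(inherits(day0_mask, "binary_mask"))
  px <- day0_mask$pixels
  if (!any(px))
    stop("cannot segment boundary: Day-0 mask is empty", call. = FALSE)
  work <- px * 1
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L,
                                shape = "disc")
    work <- EBImage::closing(work, brush)
  }
  work <- EBImage::fillHull(work)
  comp <- largest_component(work > 0.5)
  if (sum(comp) < min_area_px)
    stop(sprintf(
      "degenerate spheroid: largest component has %d px (< %d)",
      sum(comp), min_area_px), call. = FALSE)
  poly <- trace_contour(comp)
  ctr <- polygon_centroid(poly)
  align_ctr <- mask_centroid(binary_mask(largest_component(px),
                                         day0_mask$pixel_size_um))
  structure(
    list(vertices = poly, centroid = ctr, alignment_centroid = align_ctr,
         pixel_size_um = day0_mask$pixel_size_um,
         source_id = day0_mask$id, translation = c(x = 0, y = 0)),
    class = "spheroid_boundary")
}

#' @export
print.spheroid_boundary <- function(x, ...) {
  cat(sprintf(
    "<spheroid_boundary> %s: %d vertices, centroid (%.2f, %.2f) px, shift (%.2f, %.2f) px\n",
    x$source_id, nrow(x$vertices), x$centroid[1], x$centroid[2],
    x$translation[1], x$translation[2]))
  invisible(x)
}

# Outer contour of a logical matrix at the 0.5 iso-level, as an ordered
# (x, y) polygon in pixel-center coordinates. The matrix is zero-padded
# so contours are always closed; among multiple contours the one with
# the largest enclosed area is returned.
trace_contour <- function(comp) {
  h <- nrow(comp); w <- ncol(comp)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- comp * 1
  cl <- grDevices::contourLines(x = -1:w, y = -1:h, z = t(pad),
                                levels = 0.5)
  if (length(cl) == 0L)
    stop("contour tracing failed on non-empty component", call. = FALSE)
  areas <- vapply(cl, function(cc) abs(polygon_signed_area(cc$x, cc$y)),
                  numeric(1))
  best <- cl[[which.max(areas)]]
  vx <- best$x; vy <- best$y
  n <- length(vx)
  # contourLines closes the loop by repeating the first vertex; drop it
  if (n > 1L && vx[1] == vx[n] && vy[1] == vy[n]) {
    vx <- vx[-n]; vy <- vy[-n]
  }
  cbind(x = vx, y = vy)
}

polygon_signed_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  sum(vx[j] * vy - vx * vy[j]) / 2
}

#' Area of a boundary polygon in pixels^2
#' @param boundary A `spheroid_boundary`.
#' @export
boundary_area_px2 <- function(boundary) {
  abs(polygon_signed_area(boundary$vertices[, 1], boundary$vertices[, 2]))
}

# Shoelace area centroid of a simple polygon.
polygon_centroid <- function(poly) {
  vx <- poly[, 1]; vy <- poly[, 2]
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  cr <- vx[j] * vy - vx * vy[j]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps)
    return(c(x = mean(vx), y = mean(vy)))
  c(x = sum((vx[j] + vx) * cr) / (6 * a),
    y = sum((vy[j] + vy) * cr) / (6 * a))
}

#' Align a Day-0 boundary onto a Day-2 mask by centroid overlap
#'
#' The boundary is translated by the difference between the mask-pixel
#' centroid of the largest connected component of the Day-2 mask (the
#' spheroid bulk, so scattered invading nuclei do not bias the overlap)
#' and the Day-0 alignment centroid. No rotation or scaling is applied.
#'
#' @param boundary A `spheroid_boundary`.
#' @param day2_mask A non-empty [binary_mask].
#' @return The translated `spheroid_boundary`.
#' @export
align_boundary <- function(boundary, day2_mask) {
  stopifnot(inherits(boundary, "spheroid_boundary"),
            inherits(day2_mask, "binary_mask"))
  if (!any(day2_mask$pixels))
    stop("cannot align boundary: Day-2 mask is empty", call. = FALSE)
  bulk <- largest_component(day2_mask$pixels)
  c2 <- mask_centroid(binary_mask(bulk, day2_mask$pixel_size_um))
  tr <- c2 - boundary$alignment_centroid
  translate_boundary(boundary, tr)
}

translate_boundary <- function(boundary, tr) {
  boundary$vertices[, 1] <- boundary$vertices[, 1] + tr[1]
  boundary$vertices[, 2] <- boundary$vertices[, 2] + tr[2]
  boundary$centroid <- boundary$centroid + tr
  boundary$alignment_centroid <- boundary$alignment_centroid + tr
  boundary$translation <- boundary$translation + tr
  boundary
}

#' Point-in-boundary test
#'
#' Even-odd (ray casting) point-in-polygon test; points exactly on an
#' edge count as inside.
#'
#' @param boundary A `spheroid_boundary`.
#' @param x,y Point coordinates (vectorized).
#' @return Logical vector.
#' @export
point_in_boundary <- function(boundary, x, y) {
  stopifnot(inherits(boundary, "spheroid_boundary"))
  point_in_polygon(x, y, boundary$vertices[, 1], boundary$vertices[, 2])
}

point_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  inside <- logical(length(px))
  onedge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    ex <- xj - xi; ey <- yj - yi
    l2 <- ex * ex + ey * ey
    if (l2 > 0) {
      t <- ((px - xi) * ex + (py - yi) * ey) / l2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (xi + t * ex - px)^2 + (yi + t * ey - py)^2
      onedge <- onedge | d2 <= eps * eps
    } else {
      onedge <- onedge | ((px - xi)^2 + (py - yi)^2) <= eps * eps
    }
    crosses <- ((yi > py) != (yj > py))
    xint <- xi + (py - yi) * ex / ey  # only used where crosses is TRUE
    cross <- crosses & (px < xint)
    cross[is.na(cross)] <- FALSE
    inside <- xor(inside, cross)
    j <- i
  }
  inside | onedge
}

#' Radial distance from exterior points to the boundary
#'
#' For each exterior point `p`, casts the ray from the boundary centroid
#' through `p` and intersects it with every polygon edge; among
#' intersections at ray parameter `t` in `(0, t_p]` (`t_p` = parameter
#' of `p` itself) the **last** crossing before `p` is taken as the
#' boundary hit, and the distance is `|p - hit|`. This measures how far
#' the pixel lies beyond the outermost boundary edge crossed on its way
#' out. If no intersection is found (numerically degenerate ray), the
#' minimum Euclidean distance to any polygon edge is used and the point
#' is flagged.
#'
#' @param boundary A `spheroid_boundary`.
#' @param x,y Exterior point coordinates (vectorized).
#' @return A list with `distance_px`, `hit` (n x 2 matrix), and logical
#'   `fallback`.
#' @export
ray_boundary_distance <- function(boundary, x, y) {
  stopifnot(inherits(boundary, "spheroid_boundary"))
  np <- length(x)
  c0 <- unname(boundary$centroid)
  dxp <- x - c0[1]; dyp <- y - c0[2]
  tp <- sqrt(dxp^2 + dyp^2)
  if (any(tp == 0))
    stop("point coincides with the boundary centroid", call. = FALSE)
  ux <- dxp / tp; uy <- dyp / tp
  v <- boundary$vertices
  n <- nrow(v)
  ax <- v[, 1]; ay <- v[, 2]
  nx <- c(ax[-1], ax[1]); ny <- c(ay[-1], ay[1])
  eps <- 1e-9
  tbest <- rep(-Inf, np)
  for (i in seq_len(n)) {
    ex <- nx[i] - ax[i]; ey <- ny[i] - ay[i]
    wx <- ax[i] - c0[1]; wy <- ay[i] - c0[2]
    denom <- ux * ey - uy * ex
    t <- (wx * ey - wy * ex) / denom
    s <- (wx * uy - wy * ux) / denom
    ok <- is.finite(t) & is.finite(s) &
      s >= -eps & s <= 1 + eps & t > eps & t <= tp + eps
    upd <- ok & t > tbest
    tbest[upd] <- t[upd]
  }
  fallback <- !is.finite(tbest)
  d <- pmax(tp - tbest, 0)
  hx <- c0[1] + tbest * ux
  hy <- c0[2] + tbest * uy
  if (any(fallback)) {
    md <- min_edge_distance(x[fallback], y[fallback], ax, ay, nx, ny)
    d[fallback] <- md$d
    hx[fallback] <- md$hx
    hy[fallback] <- md$hy
  }
  list(distance_px = d, hit = cbind(x = hx, y = hy), fallback = fallback)
}

min_edge_distance <- function(px, py, ax, ay, bx, by) {
  best <- rep(Inf, length(px))
  hx <- hy <- rep(NA_real_, length(px))
  for (i in seq_along(ax)) {
    ex <- bx[i] - ax[i]; ey <- by[i] - ay[i]
    l2 <- ex * ex + ey * ey
    t <- if (l2 > 0) ((px - ax[i]) * ex + (py - ay[i]) * ey) / l2 else 0
    t <- pmin(pmax(t, 0), 1)
    qx <- ax[i] + t * ex; qy <- ay[i] + t * ey
    d2 <- (qx - px)^2 + (qy - py)^2
    upd <- d2 < best^2
    best[upd] <- sqrt(d2[upd]); hx[upd] <- qx[upd]; hy[upd] <- qy[upd]
  }
  list(d = best, hx = hx, hy = hy)
}

#' Export boundary vertices and alignment metadata
#'
#' Writes the polygon as a `x_px,y_px` CSV plus a JSON sidecar holding
#' the centroid and the translation applied during alignment (audit
#' trail for overlay figures).
#'
#' @param boundary A `spheroid_boundary`.
#' @param csv_path Vertex CSV path; the sidecar is written next to it
#'   with extension `.json`.
#' @export
export_boundary <- function(boundary, csv_path) {
  stopifnot(inherits(boundary, "spheroid_boundary"))
  df <- data.frame(x_px = boundary$vertices[, 1],
                   y_px = boundary$vertices[, 2])
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  side <- list(source_id = boundary$source_id,
               centroid_px = as.numeric(boundary$centroid),
               alignment_centroid_px =
                 as.numeric(boundary$alignment_centroid),
               translation_px = as.numeric(boundary$translation),
               pixel_size_um = boundary$pixel_size_um,
               n_vertices = nrow(boundary$vertices))
  jsonlite::write_json(side,
                       paste0(tools::file_path_sans_ext(csv_path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
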