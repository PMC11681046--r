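# Grayscale -> binary nuclei masks: contrast stretch, optional background
# subtraction, global threshold, artifact-mask correction, circular field
# mask.

#' Binarization configuration
#'
#' @param threshold Global threshold on the \[0, 1\] intensity scale; a
#'   pixel is foreground iff its (enhanced) intensity is strictly greater.
#'   Default 0.16, a value that works well for Hoechst-stained nuclear
#'   maximum projections.
#' @param contrast_percentiles Length-2 percentile pair `(low, high)` for
#'   the linear contrast stretch; default `c(1, 99)` (robust to hot
#'   pixels).
#' @param background_sigma_px Gaussian sigma (pixels) of the smooth
#'   background estimate subtracted before thresholding; 0 (default)
#'   disables background subtraction.
#' @param apply_circular_mask Crop the binarized image to the largest
#'   centered circle to avoid bias towards the frame's long axis and
#'   corners (default `TRUE`).
#' @return An object of class `binarize_config`.
#' @export
binarize_config <- function(threshold = 0.16,
                            contrast_percentiles = c(1, 99),
                            background_sigma_px = 0,
                            apply_circular_mask = TRUE) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("`threshold` must be a single number in [0, 1]", call. = FALSE)
  cp <- as.numeric(contrast_percentiles)
  if (length(cp) != 2L || cp[1] < 0 || cp[2] > 100 || cp[1] >= cp[2])
    stop("`contrast_percentiles` must satisfy 0 <= low < high <= 100",
         call. = FALSE)
  if (!is.numeric(background_sigma_px) || background_sigma_px < 0)
    stop("`background_sigma_px` must be >= 0", call. = FALSE)
  structure(list(threshold = threshold, contrast_percentiles = cp,
                 background_sigma_px = as.numeric(background_sigma_px),
                 apply_circular_mask = isTRUE(apply_circular_mask)),
            class = "binarize_config")
}

#' Percentile-clipped linear contrast stretch
#'
#' Maps the low-percentile intensity to 0 and the high-percentile
#' intensity to 1, clipping to \[0, 1\]. Constant (zero dynamic range)
#' images are returned unchanged.
#'
#' @param img A [calibrated_image].
#' @param contrast_percentiles Percentile pair `(low, high)`.
#' @return A [calibrated_image].
#' @export
enhance_contrast <- function(img, contrast_percentiles = c(1, 99)) {
  stopifnot(inherits(img, "calibrated_image"))
  cp <- as.numeric(contrast_percentiles)
  if (length(cp) != 2L || cp[1] < 0 || cp[2] > 100 || cp[1] >= cp[2])
    stop("`contrast_percentiles` must satisfy 0 <= low < high <= 100",
         call. = FALSE)
  q <- stats::quantile(img$pixels, probs = cp / 100, names = FALSE,
                       type = 7)
  if (q[2] <= q[1]) return(img)  # degenerate: constant image
  out <- (img$pixels - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  calibrated_image(out, img$pixel_size_um, img$id, img$timepoint)
}

#' Gaussian background subtraction
#'
#' Estimates a smooth background as a Gaussian blur (replicated-edge
#' convolution) with the stated sigma, subtracts it, clips at 0 and
#' rescales the maximum back to the original maximum. `sigma = 0` is the
#' identity.
#'
#' @param img A [calibrated_image].
#' @param background_sigma_px Gaussian sigma in pixels (>= 0).
#' @return A [calibrated_image].
#' @export
subtract_background <- function(img, background_sigma_px) {
  stopifnot(inherits(img, "calibrated_image"))
  if (background_sigma_px < 0)
    stop("`background_sigma_px` must be >= 0", call. = FALSE)
  if (background_sigma_px == 0) return(img)
  bg <- gaussian_blur(img$pixels, background_sigma_px)
  out <- img$pixels - bg
  out[out < 0] <- 0
  mx_orig <- max(img$pixels)
  mx_new <- max(out)
  if (mx_new > 0) out <- out * (mx_orig / mx_new)
  out[out > 1] <- 1
  calibrated_image(out, img$pixel_size_um, img$id, img$timepoint)
}

# Gaussian smoothing with replicated edges (so flat fields stay flat and
# subtract to exactly zero).
gaussian_blur <- function(px, sigma) {
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  # the kernel cannot exceed the image; cap at the largest odd fit
  cap <- min(dim(px))
  if (radius > cap) radius <- cap - 1L + cap %% 2L
  brush <- EBImage::makeBrush(radius, shape = "gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(px, brush, boundary = "replicate"))
}

#' Apply a global threshold
#'
#' A pixel is foreground iff its intensity is strictly greater than the
#' threshold (so `threshold = 1` always yields an empty mask).
#'
#' @param img A [calibrated_image].
#' @param threshold Scalar in \[0, 1\].
#' @return A [binary_mask].
#' @export
apply_threshold <- function(img, threshold = 0.16) {
  stopifnot(inherits(img, "calibrated_image"))
  binary_mask(img$pixels > threshold, img$pixel_size_um, img$id,
              img$timepoint)
}

#' Remove user-marked artifacts from a mask
#'
#' Foreground in `artifact_mask` is erased from `mask`
#' (`mask AND NOT artifact`). This replaces interactive manual erasing
#' with a reproducible file-based correction.
#'
#' @param mask,artifact_mask [binary_mask] objects of identical shape.
#' @return A [binary_mask].
#' @export
apply_artifact_mask <- function(mask, artifact_mask) {
  stopifnot(inherits(mask, "binary_mask"),
            inherits(artifact_mask, "binary_mask"))
  if (!identical(dim(mask$pixels), dim(artifact_mask$pixels)))
    stop("artifact mask shape does not match image shape", call. = FALSE)
  binary_mask(mask$pixels & !artifact_mask$pixels, mask$pixel_size_um,
              mask$id, mask$timepoint)
}

#' Apply the circular field mask
#'
#' Pixels whose center lies at Euclidean distance greater than
#' `min(height, width) / 2` from the geometric image center
#' (`((W-1)/2, (H-1)/2)` in pixel-center coordinates) are set to
#' background. Prevents bias towards the frame's long axis and corners.
#'
#' @param mask A [binary_mask].
#' @return A [binary_mask].
#' @export
apply_circular_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  h <- nrow(mask$pixels); w <- ncol(mask$pixels)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  r <- min(h, w) / 2
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  keep <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  binary_mask(mask$pixels & keep, mask$pixel_size_um, mask$id,
              mask$timepoint)
}

#' Full binarization pipeline
#'
#' Composes, in order: contrast enhancement, background subtraction (if
#' `background_sigma_px > 0`), global thresholding, artifact-mask
#' correction (if a mask is given), circular field mask (if enabled).
#'
#' @param img A [calibrated_image].
#' @param cfg A [binarize_config].
#' @param artifact_mask Optional [binary_mask] of pixels to erase.
#' @return A [binary_mask].
#' @export
binarize_pipeline <- function(img, cfg = binarize_config(),
                              artifact_mask = NULL) {
  stopifnot(inherits(img, "calibrated_image"),
            inherits(cfg, "binarize_config"))
  x <- enhance_contrast(img, cfg$contrast_percentiles)
  x <- subtract_background(x, cfg$background_sigma_px)
  m <- apply_threshold(x, cfg$threshold)
  if (!is.null(artifact_mask)) m <- apply_artifact_mask(m, artifact_mask)
  if (cfg$apply_circular_mask) m <- apply_circular_mask(m)
  m
}
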