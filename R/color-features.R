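#' Convert an RGB image to 8-bit grayscale
#'
#' Weighted-luminance conversion: each pixel becomes
#' `0.2989 R + 0.5870 G + 0.1140 B`, rounded half-away-from-zero to an
#' integer and clamped to \[0, 255\]. The weights sum to 0.9999, so the
#' grayscale value always lies within one unit of the channel range
#' `[min(R,G,B), max(R,G,B)]`.
#'
#' @param img an [rgb_image()].
#' @return Integer matrix (H x W) of brightness values in \[0, 255\].
#' @export
#' @examples
#' px <- array(c(100, 150, 50), dim = c(1, 1, 3))[rep(1, 2), rep(1, 2), ]
#' to_grayscale(rgb_image(array(px, c(2, 2, 3))))
to_grayscale <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  p <- img$pixels
  gs <- 0.2989 * p[, , 1L] + 0.5870 * p[, , 2L] + 0.1140 * p[, , 3L]
  gs <- round_half_up(gs)
  gs[gs < 0L] <- 0L
  gs[gs > 255L] <- 255L
  storage.mode(gs) <- "integer"
  gs
}

#' Per-channel mean and median brightness
#'
#' Arithmetic mean and median of each RGB channel over all pixels. Medians
#' for even pixel counts are the mean of the two middle order statistics.
#'
#' @param img an [rgb_image()].
#' @return Named numeric vector `R_MEAN, G_MEAN, B_MEAN, R_MEDIAN,
#'   G_MEDIAN, B_MEDIAN`.
#' @export
channel_stats <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  p <- img$pixels
  c(R_MEAN = mean(p[, , 1L]), G_MEAN = mean(p[, , 2L]), B_MEAN = mean(p[, , 3L]),
    R_MEDIAN = median(p[, , 1L]), G_MEDIAN = median(p[, , 2L]),
    B_MEDIAN = median(p[, , 3L]))
}

#' Mean and median brightness of a grayscale image
#'
#' @param gs integer matrix from [to_grayscale()].
#' @return Named numeric vector `GS_MEAN, GS_MEDIAN`.
#' @export
grayscale_stats <- function(gs) {
  gs <- validate_gray(gs)
  c(GS_MEAN = mean(gs), GS_MEDIAN = median(gs))
}

#' Binarize a grayscale image
#'
#' A pixel is white (1) iff its normalized value `pixel / 255` is strictly
#' greater than `threshold`; otherwise black (0). Pipeline use fixes the
#' thresholds at 0.05, 0.10, 0.15 and 0.20, but any threshold in (0, 1)
#' is accepted.
#'
#' @param gs integer matrix from [to_grayscale()].
#' @param threshold real in (0, 1).
#' @return Integer 0/1 matrix with attribute `threshold`.
#' @export
binarize <- function(gs, threshold) {
  gs <- validate_gray(gs)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single value strictly inside (0, 1)",
         call. = FALSE)
  }
  b <- (gs / 255 > threshold) + 0L
  attr(b, "threshold") <- threshold
  b
}

#' Percentage of white pixels in a binarized image
#'
#' @param bin 0/1 matrix from [binarize()].
#' @return Percentage in \[0, 100\].
#' @export
white_percentage <- function(bin) {
  if (!is.matrix(bin) || !all(bin %in% c(0L, 1L))) {
    stop("`bin` must be a 0/1 matrix", call. = FALSE)
  }
  100 * sum(bin) / length(bin)
}

validate_gray <- function(gs) {
  if (!is.matrix(gs) || !is.numeric(gs)) {
    stop("grayscale image must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(gs) || any(gs < 0) || any(gs > 255) || any(gs != round(gs))) {
    stop("grayscale values must be integers in [0, 255]", call. = FALSE)
  }
  storage.mode(gs) <- "integer"
  gs
}
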