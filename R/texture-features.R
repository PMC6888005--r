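# GLCM texture analysis: symmetric 8-level co-occurrence matrices for the
# four 1-pixel neighborhoods (0, 45, 90, 135 degrees), summarized by
# contrast, correlation, energy and homogeneity, plus 256-bin histogram
# entropy of the grayscale image.

glcm_directions <- c("0", "45", "90", "135")

# row/column offsets; origin top-left, rows indexed downward
direction_offset <- function(direction) {
  switch(as.character(direction),
         `0`   = c(0L,  1L),
         `45`  = c(-1L, 1L),
         `90`  = c(-1L, 0L),
         `135` = c(-1L, -1L),
         stop("direction must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Quantize a grayscale image into brightness classes
#'
#' Equal-width binning of the fixed range \[0, 255\]:
#' `level = floor(pixel * levels / 256) + 1`, so pixel 0 maps to level 1 and
#' pixel 255 to level `levels`. The fixed range (rather than a per-image
#' min-max stretch) keeps texture features comparable across images of
#' differing overall brightness; min-max stretching is available for
#' sensitivity checks.
#'
#' @param gs integer matrix from [to_grayscale()].
#' @param levels number of brightness classes (default 8).
#' @param range `"fixed"` (default) bins \[0, 255\]; `"min_max"` bins the
#'   image's own \[min, max\] (a constant image maps to level 1).
#' @return Integer matrix of levels in \[1, `levels`\].
#' @export
quantize_gray <- function(gs, levels = 8L, range = c("fixed", "min_max")) {
  gs <- validate_gray(gs)
  range <- match.arg(range)
  if (!is.numeric(levels) || length(levels) != 1L || levels < 2L) {
    stop("`levels` must be a single integer >= 2", call. = FALSE)
  }
  levels <- as.integer(levels)
  if (range == "fixed") {
    q <- floor(gs * levels / 256) + 1L
  } else {
    lo <- min(gs); hi <- max(gs)
    if (hi == lo) {
      q <- matrix(1L, nrow(gs), ncol(gs))
    } else {
      q <- floor((gs - lo) * levels / (hi - lo + 1L)) + 1L
    }
  }
  q[q > levels] <- levels
  storage.mode(q) <- "integer"
  q
}

#' Build a symmetric gray-level co-occurrence matrix
#'
#' Counts, for every pixel and its 1-pixel neighbor in the given direction,
#' the pair of quantized levels in both orders (symmetric accumulation), and
#' normalizes the counts to a joint probability table.
#'
#' @param q integer matrix of quantized levels from [quantize_gray()].
#' @param direction one of `0`, `45`, `90`, `135` (degrees).
#' @param levels number of brightness classes (matrix is `levels` square).
#' @return An object of class `glcm`: list with `p` (normalized matrix
#'   summing to 1), `raw_counts`, `direction`, `levels`.
#' @export
build_glcm <- function(q, direction, levels = 8L) {
  if (!is.matrix(q) || any(q < 1L) || any(q > levels) || any(q != round(q))) {
    stop("`q` must be a matrix of integer levels in [1, levels]",
         call. = FALSE)
  }
  off <- direction_offset(direction)
  h <- nrow(q); w <- ncol(q)
  if (h - abs(off[1]) < 1L || w - abs(off[2]) < 1L) {
    stop("grid has no valid neighbor pair in direction ", direction,
         call. = FALSE)
  }
  r1 <- max(1L, 1L - off[1]):min(h, h - off[1])
  c1 <- max(1L, 1L - off[2]):min(w, w - off[2])
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- matrix(tabulate((a - 1L) * levels + b, nbins = levels * levels),
                   nrow = levels, ncol = levels, byrow = TRUE)
  counts <- counts + t(counts)
  structure(list(p = counts / sum(counts),
                 raw_counts = counts,
                 direction = as.character(direction),
                 levels = as.integer(levels)),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> %d levels, direction %s deg, %d pair counts\n",
              x$levels, x$direction, sum(x$raw_counts)))
  print(round(x$p, 4)); invisible(x)
}

#' Marginal moments of a GLCM
#'
#' Row/column marginal means and standard deviations of the joint level
#' distribution; for the symmetric matrices built here the row and column
#' moments coincide.
#'
#' @param g a `glcm` from [build_glcm()].
#' @return List with `mu_i`, `mu_j`, `sigma_i`, `sigma_j`.
#' @export
glcm_moments <- function(g) {
  stopifnot(inherits(g, "glcm"))
  i <- matrix(seq_len(g$levels), g$levels, g$levels)
  j <- t(i)
  mu_i <- sum(i * g$p); mu_j <- sum(j * g$p)
  list(mu_i = mu_i, mu_j = mu_j,
       sigma_i = sqrt(sum((i - mu_i)^2 * g$p)),
       sigma_j = sqrt(sum((j - mu_j)^2 * g$p)))
}

#' GLCM contrast
#'
#' `sum (i - j)^2 p(i, j)`; 0 for a constant image, at most
#' `(levels - 1)^2` (49 for 8 levels).
#' @param g a `glcm`.
#' @return Non-negative real.
#' @export
glcm_contrast <- function(g) {
  stopifnot(inherits(g, "glcm"))
  i <- matrix(seq_len(g$levels), g$levels, g$levels)
  sum((i - t(i))^2 * g$p)
}

#' GLCM correlation
#'
#' `sum (i - mu_i)(j - mu_j) p(i, j) / (sigma_i sigma_j)`, in \[-1, 1\].
#' For a single-level (constant) image the marginal deviations are zero and
#' the statistic is undefined: `NA` is returned, never a silent 0 or 1.
#' @param g a `glcm`.
#' @return Real in \[-1, 1\], or `NA` when undefined.
#' @export
glcm_correlation <- function(g) {
  stopifnot(inherits(g, "glcm"))
  m <- glcm_moments(g)
  denom <- m$sigma_i * m$sigma_j
  if (denom == 0) return(NA_real_)
  i <- matrix(seq_len(g$levels), g$levels, g$levels)
  sum((i - m$mu_i) * (t(i) - m$mu_j) * g$p) / denom
}

#' GLCM energy (angular second moment)
#'
#' `sum p(i, j)^2`, in (0, 1\]; equals 1 iff all mass sits in one cell.
#' @param g a `glcm`.
#' @return Real in (0, 1].
#' @export
glcm_energy <- function(g) {
  stopifnot(inherits(g, "glcm"))
  sum(g$p^2)
}

#' GLCM homogeneity (inverse difference)
#'
#' `sum p(i, j) / (1 + |i - j|)`, in (0, 1\]; equals 1 iff all mass is on
#' the diagonal. The absolute value in the denominator is required: with a
#' signed difference the term is undefined whenever `j = i + 1`.
#' @param g a `glcm`.
#' @return Real in (0, 1].
#' @export
glcm_homogeneity <- function(g) {
  stopifnot(inherits(g, "glcm"))
  i <- matrix(seq_len(g$levels), g$levels, g$levels)
  sum(g$p / (1 + abs(i - t(i))))
}

#' Histogram entropy of a grayscale image
#'
#' Shannon entropy, in bits, of the 256-bin brightness histogram:
#' `-sum f_k log2 f_k` over brightness values k = 0..255 with `f_k` the
#' proportion of pixels at brightness k (`0 log 0 = 0`). Ranges from 0
#' (constant image) to 8 (all brightness values equally frequent).
#' @param gs integer matrix from [to_grayscale()].
#' @return Real in \[0, 8\].
#' @export
gray_entropy <- function(gs) {
  gs <- validate_gray(gs)
  f <- tabulate(gs + 1L, nbins = 256L) / length(gs)
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' The five texture parameters of an image
#'
#' ENTROPY is computed from the 256-bin grayscale histogram. CONTRAST,
#' CORRELATION, ENERGY and HOMOGENEITY are each computed separately on the
#' four directional GLCMs and then arithmetically averaged (per-direction
#' first, then average — not computed on a pooled matrix, which would give
#' different values). If CORRELATION is undefined in some directions it is
#' averaged over the defined ones; if undefined in all four it propagates
#' as `NA`.
#'
#' @param gs integer matrix from [to_grayscale()].
#' @param levels brightness classes for the GLCMs (default 8).
#' @param quantization `"fixed"` or `"min_max"`, see [quantize_gray()].
#' @return Named numeric vector `ENTROPY, CONTRAST, CORRELATION, ENERGY,
#'   HOMOGENEITY`.
#' @export
texture_vector <- function(gs, levels = 8L, quantization = c("fixed", "min_max")) {
  gs <- validate_gray(gs)
  quantization <- match.arg(quantization)
  if (nrow(gs) < 2L || ncol(gs) < 2L) {
    stop("image must be at least 2 x 2 for GLCM analysis", call. = FALSE)
  }
  q <- quantize_gray(gs, levels = levels, range = quantization)
  per_dir <- vapply(glcm_directions, function(d) {
    g <- build_glcm(q, d, levels = levels)
    c(contrast = glcm_contrast(g),
      correlation = glcm_correlation(g),
      energy = glcm_energy(g),
      homogeneity = glcm_homogeneity(g))
  }, numeric(4))
  corr <- per_dir["correlation", ]
  corr_mean <- if (all(is.na(corr))) NA_real_ else mean(corr, na.rm = TRUE)
  c(ENTROPY = gray_entropy(gs),
    CONTRAST = mean(per_dir["contrast", ]),
    CORRELATION = corr_mean,
    ENERGY = mean(per_dir["energy", ]),
    HOMOGENEITY = mean(per_dir["homogeneity", ]))
}
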