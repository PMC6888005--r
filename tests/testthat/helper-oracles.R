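# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written in the most literal way possible (double loops,
# explicit enumerations) so it cannot share a bug with the vectorized
# implementations it checks.

# ---- GLCM oracles -----------------------------------------------------------

oracle_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                       `90` = c(-1L, 0L), `135` = c(-1L, -1L))

# symmetric pair counting by explicit double loop
oracle_glcm_counts <- function(q, direction, levels = 8L) {
  off <- oracle_offsets[[as.character(direction)]]
  counts <- matrix(0L, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1L && r2 <= nrow(q) && c2 >= 1L && c2 <= ncol(q)) {
        a <- q[r, cc]; b <- q[r2, c2]
        counts[a, b] <- counts[a, b] + 1L
        counts[b, a] <- counts[b, a] + 1L
      }
    }
  }
  counts
}

# direct elementwise summation of the four GLCM statistics
oracle_haralick <- function(p) {
  L <- nrow(p)
  mu_i <- 0; mu_j <- 0
  for (i in 1:L) for (j in 1:L) { mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j] }
  v_i <- 0; v_j <- 0; contrast <- 0; energy <- 0; homog <- 0; cov <- 0
  for (i in 1:L) {
    for (j in 1:L) {
      v_i <- v_i + (i - mu_i)^2 * p[i, j]
      v_j <- v_j + (j - mu_j)^2 * p[i, j]
      contrast <- contrast + (i - j)^2 * p[i, j]
      energy <- energy + p[i, j]^2
      homog <- homog + p[i, j] / (1 + abs(i - j))
      cov <- cov + (i - mu_i) * (j - mu_j) * p[i, j]
    }
  }
  corr <- if (v_i * v_j > 0) cov / (sqrt(v_i) * sqrt(v_j)) else NA_real_
  list(mu_i = mu_i, mu_j = mu_j, sigma_i = sqrt(v_i), sigma_j = sqrt(v_j),
       contrast = contrast, correlation = corr, energy = energy,
       homogeneity = homog)
}

# ---- Mann-Whitney permutation oracle ---------------------------------------

# U by explicit pair counting (not rank sums)
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) u <- u + 1 else if (xi == yj) u <- u + 0.5
  }
  u
}

# exact two-sided p over every assignment of the pooled values to groups
oracle_mw_p <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y); n <- length(pooled)
  mid <- n1 * (n - n1) / 2
  t_obs <- abs(oracle_u(x, y) - mid)
  sets <- utils::combn(n, n1)
  hits <- 0
  for (k in seq_len(ncol(sets))) {
    xs <- pooled[sets[, k]]; ys <- pooled[-sets[, k]]
    if (abs(oracle_u(xs, ys) - mid) >= t_obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(sets)
}

# ---- image fixtures ---------------------------------------------------------

random_gray <- function(h, w) matrix(sample(0:255, h * w, replace = TRUE), h, w)

random_rgb_image <- function(h, w, ...) {
  rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)), ...)
}

checkerboard_gray <- function(n = 8L) {
  outer(seq_len(n), seq_len(n), function(r, c) ifelse((r + c) %% 2 == 0, 0L, 255L))
}

# counterclockwise quarter rotation
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

random_feature_table <- function(n_experiments = 3L, n_images = 4L) {
  rows <- list()
  for (e in seq_len(n_experiments)) {
    for (i in seq_len(n_images)) {
      vals <- as.list(stats::setNames(runif(17, 0, 100), compost_parameters()))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        experiment_id = sprintf("EXP%d", e),
        source_id = sprintf("img%02d", i), !!!vals)
    }
  }
  dplyr::bind_rows(rows)
}

# Hand-constructed 2 x 2 RGB 16-bit little-endian TIFF, assembled field by
# field from the format layout (independent of the package's writer).
# Pixel values, row-major, RGB interleaved:
#   (0, 257, 513), (65535, 32896, 128), (1000, 2000, 3000), (514, 515, 516)
tiff16_fixture_path <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, x %/% 16777216))
  entry <- function(tag, type, count, value_bytes) {
    c(u16(tag), u16(type), u32(count), value_bytes)
  }
  short_val <- function(x) c(u16(x), u16(0))
  ifd_off <- 8L
  n_entries <- 9L
  bps_off <- ifd_off + 2L + 12L * n_entries + 4L   # 122
  data_off <- bps_off + 6L                          # 128
  bytes <- c(
    charToRaw("II"), u16(42L), u32(ifd_off),
    u16(n_entries),
    entry(256L, 4L, 1L, u32(2L)),          # ImageWidth
    entry(257L, 4L, 1L, u32(2L)),          # ImageLength
    entry(258L, 3L, 3L, u32(bps_off)),     # BitsPerSample -> offset
    entry(259L, 3L, 1L, short_val(1L)),    # Compression: none
    entry(262L, 3L, 1L, short_val(2L)),    # Photometric: RGB
    entry(273L, 4L, 1L, u32(data_off)),    # StripOffsets
    entry(277L, 3L, 1L, short_val(3L)),    # SamplesPerPixel
    entry(278L, 4L, 1L, u32(2L)),          # RowsPerStrip
    entry(279L, 4L, 1L, u32(24L)),         # StripByteCounts
    u32(0L),                               # no next IFD
    u16(16L), u16(16L), u16(16L),          # BitsPerSample values
    unlist(lapply(c(0L, 257L, 513L, 65535L, 32896L, 128L,
                    1000L, 2000L, 3000L, 514L, 515L, 516L), u16))
  )
  path <- file.path(dir, "fixture16.tif")
  writeBin(bytes, path)
  path
}

tiff16_fixture_pixels <- function() {
  vals <- matrix(c(0, 257, 513, 65535, 32896, 128,
                   1000, 2000, 3000, 514, 515, 516),
                 ncol = 3, byrow = TRUE)
  arr <- array(0, c(2, 2, 3))
  arr[1, 1, ] <- vals[1, ]; arr[1, 2, ] <- vals[2, ]
  arr[2, 1, ] <- vals[3, ]; arr[2, 2, ] <- vals[4, ]
  arr
}
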