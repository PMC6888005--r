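test_that("quantization bins the fixed [0, 255] range into equal widths", {
  g <- matrix(c(0L, 31L, 32L, 255L), 2, 2)
  q <- quantize_gray(g)
  expect_identical(as.integer(q), c(1L, 1L, 2L, 8L))  # column-major order
  expect_true(all(quantize_gray(matrix(100L, 3, 3)) == 4L))
  expect_error(quantize_gray(g, levels = 1), ">= 2")
  # min-max stretch maps the image's own range; constant image -> level 1
  qm <- quantize_gray(matrix(c(10L, 20L), 2, 2), range = "min_max")
  expect_identical(sort(unique(as.integer(qm))), c(1L, 8L))
  expect_true(all(quantize_gray(matrix(77L, 2, 2), range = "min_max") == 1L))
})

test_that("build_glcm hand example: 2x2 two-level grid, direction 0", {
  q <- matrix(c(1L, 8L, 1L, 8L), 2, 2)  # rows [1,1] and [8,8]
  g <- build_glcm(q, 0)
  expect_equal(g$p[1, 1], 0.5)
  expect_equal(g$p[8, 8], 0.5)
  expect_equal(sum(g$p), 1)
  expect_equal(sum(g$raw_counts), 4L)   # 2 horizontal pairs, doubled
})

test_that("GLCMs are normalized, symmetric, with the right pair totals", {
  set.seed(4)
  for (rep in 1:10) {
    h <- sample(2:9, 1); w <- sample(2:9, 1)
    q <- matrix(sample(1:8, h * w, replace = TRUE), h, w)
    for (d in c("0", "45", "90", "135")) {
      g <- build_glcm(q, d)
      expect_equal(sum(g$p), 1, tolerance = 1e-12)
      expect_identical(g$raw_counts, t(g$raw_counts))
      n_pairs <- switch(d, `0` = h * (w - 1), `90` = (h - 1) * w,
                        (h - 1) * (w - 1))
      expect_identical(sum(g$raw_counts), 2L * as.integer(n_pairs))
    }
  }
})

test_that("build_glcm and all statistics match brute-force oracles", {
  set.seed(5)
  for (rep in 1:40) {
    h <- sample(2:12, 1); w <- sample(2:12, 1)
    q <- matrix(sample(1:8, h * w, replace = TRUE), h, w)
    for (d in c("0", "45", "90", "135")) {
      g <- build_glcm(q, d)
      expect_identical(g$raw_counts, oracle_glcm_counts(q, d))
      o <- oracle_haralick(g$p)
      expect_equal(glcm_contrast(g), o$contrast, tolerance = 1e-12)
      expect_equal(glcm_energy(g), o$energy, tolerance = 1e-12)
      expect_equal(glcm_homogeneity(g), o$homogeneity, tolerance = 1e-12)
      expect_equal(glcm_correlation(g), o$correlation, tolerance = 1e-12)
      m <- glcm_moments(g)
      expect_equal(m$mu_i, o$mu_i, tolerance = 1e-12)
      expect_equal(m$sigma_j, o$sigma_j, tolerance = 1e-12)
    }
  }
})

test_that("symmetric GLCM moments coincide and sit in [1, 8]", {
  set.seed(6)
  for (rep in 1:10) {
    q <- matrix(sample(1:8, 36, replace = TRUE), 6, 6)
    m <- glcm_moments(build_glcm(q, sample(c("0", "45", "90", "135"), 1)))
    expect_identical(m$mu_i, m$mu_j)
    expect_identical(m$sigma_i, m$sigma_j)
    expect_true(m$mu_i >= 1 && m$mu_i <= 8)
  }
})

test_that("analytic values hold for constant and checkerboard images", {
  # constant image: all mass in one diagonal cell
  qc <- quantize_gray(matrix(200L, 5, 5))
  g <- build_glcm(qc, 0)
  expect_equal(glcm_contrast(g), 0)
  expect_equal(glcm_energy(g), 1)
  expect_equal(glcm_homogeneity(g), 1)
  expect_true(is.na(glcm_correlation(g)))

  # 0/255 checkerboard at 0 deg: two off-diagonal cells
  q <- quantize_gray(checkerboard_gray(8))
  g <- build_glcm(q, 0)
  expect_equal(glcm_contrast(g), 49)
  expect_equal(glcm_energy(g), 0.5)
  expect_equal(glcm_homogeneity(g), 0.125)
  expect_equal(glcm_correlation(g), -1)

  # horizontal two-level stripes: every 0-deg pair is on the diagonal
  stripes <- matrix(rep(c(0L, 255L), each = 4), 8, 4)  # rows constant
  expect_equal(glcm_correlation(build_glcm(quantize_gray(stripes), 0)), 1)
})

test_that("statistic ranges hold on arbitrary inputs", {
  set.seed(7)
  for (rep in 1:30) {
    gs <- random_gray(sample(2:10, 1), sample(2:10, 1))
    tv <- texture_vector(gs)
    expect_true(tv["CONTRAST"] >= 0 && tv["CONTRAST"] <= 49)
    expect_true(tv["ENERGY"] > 0 && tv["ENERGY"] <= 1)
    expect_true(tv["HOMOGENEITY"] > 0 && tv["HOMOGENEITY"] <= 1)
    expect_true(is.na(tv["CORRELATION"]) ||
                  (tv["CORRELATION"] >= -1 - 1e-12 && tv["CORRELATION"] <= 1 + 1e-12))
    expect_true(tv["ENTROPY"] >= 0 && tv["ENTROPY"] <= 8)
  }
})

test_that("histogram entropy hits its analytic values", {
  expect_equal(gray_entropy(matrix(7L, 4, 4)), 0)
  expect_equal(gray_entropy(matrix(c(0L, 255L), 4, 4)), 1)    # binary, equal
  expect_equal(gray_entropy(matrix(0:255, 16, 16)), 8)        # uniform over 256
  # 1/4 vs 3/4 mixture: -(1/4)log2(1/4) - (3/4)log2(3/4)
  g <- matrix(c(0L, 9L, 9L, 9L), 4, 4)
  expect_equal(gray_entropy(g), -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
})

test_that("rotating the image by 90 degrees permutes directions and keeps the average", {
  set.seed(8)
  perm <- c(`0` = "90", `45` = "135", `90` = "0", `135` = "45")
  for (rep in 1:10) {
    gs <- random_gray(7, 5)
    q <- quantize_gray(gs)
    qr <- quantize_gray(rot90(gs))
    for (stat in list(glcm_contrast, glcm_energy, glcm_homogeneity)) {
      orig <- vapply(c("0", "45", "90", "135"),
                     function(d) stat(build_glcm(q, d)), numeric(1))
      rot <- vapply(c("0", "45", "90", "135"),
                    function(d) stat(build_glcm(qr, d)), numeric(1))
      expect_equal(unname(rot[perm[names(orig)]]), unname(orig),
                   tolerance = 1e-12)
      expect_equal(mean(rot), mean(orig), tolerance = 1e-12)
    }
  }
})

test_that("texture_vector averages per-direction values (not a pooled matrix)", {
  set.seed(9)
  gs <- random_gray(9, 9)
  q <- quantize_gray(gs)
  dirs <- c("0", "45", "90", "135")
  glcms <- lapply(dirs, function(d) build_glcm(q, d))
  tv <- texture_vector(gs)
  expect_equal(unname(tv["CONTRAST"]),
               mean(vapply(glcms, glcm_contrast, numeric(1))), tolerance = 1e-12)
  expect_equal(unname(tv["ENERGY"]),
               mean(vapply(glcms, glcm_energy, numeric(1))), tolerance = 1e-12)
  expect_equal(unname(tv["HOMOGENEITY"]),
               mean(vapply(glcms, glcm_homogeneity, numeric(1))), tolerance = 1e-12)
  # pooling the four matrices first gives a different energy in general
  pooled <- Reduce(`+`, lapply(glcms, function(g) g$raw_counts))
  pooled_p <- pooled / sum(pooled)
  pooled_energy <- sum(pooled_p^2)
  expect_false(isTRUE(all.equal(pooled_energy, unname(tv["ENERGY"]),
                                tolerance = 1e-6)))
})

test_that("degenerate inputs are rejected or propagate as undefined", {
  expect_error(build_glcm(matrix(1L, 1, 1), 0), "no valid neighbor pair")
  expect_error(texture_vector(matrix(5L, 1, 3)), "at least 2 x 2")
  tv <- texture_vector(matrix(16L, 4, 4))
  expect_equal(unname(tv[c("ENTROPY", "CONTRAST", "ENERGY", "HOMOGENEITY")]),
               c(0, 0, 1, 1))
  expect_true(is.na(tv["CORRELATION"]))
})
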