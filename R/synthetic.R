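# Seeded synthetic compost-sample images. The real material is a dark,
# spatially correlated matrix (decomposed sludge/straw mixture) with bright
# elongated straw fragments; the unfavorable class is brighter overall and
# carries more undecomposed straw. The generator reproduces exactly that
# structure: a shared smoothed-Gaussian luminance field scaled per channel,
# a per-image brightness jitter (across-image variation), and Poisson
# bright streaks.

#' Specification of one synthetic image class
#'
#' @param label `"favorable"` or `"unfavorable"`.
#' @param channel_means target per-channel means (R, G, B) of the generated
#'   composite image, in \[0, 255\].
#' @param channel_sds within-image pixel standard deviations per channel.
#' @param between_image_sds SDs of the per-image brightness jitter (one
#'   shared standard normal per image scaled per channel) — this is what
#'   makes group SDs of per-image means realistic.
#' @param smoothing_scale Gaussian kernel scale in pixels controlling
#'   spatial autocorrelation (default 3).
#' @param streak_density expected bright streaks per 10^4 pixels.
#' @param streak_brightness (R, G, B) brightness of streak pixels.
#' @param streak_length_range,streak_width_range integer pixel ranges.
#' @param mean_offset per-channel additive correction applied to the base
#'   field so the composite (streaks + zero-clamping included) hits
#'   `channel_means`; calibrated once by simulation for the default specs.
#' @return A list of class `class_spec`.
#' @export
class_spec <- function(label,
                       channel_means,
                       channel_sds,
                       between_image_sds = c(0, 0, 0),
                       smoothing_scale = 3,
                       streak_density = 0,
                       streak_brightness = c(170, 150, 110),
                       streak_length_range = c(8L, 40L),
                       streak_width_range = c(1L, 3L),
                       mean_offset = c(0, 0, 0)) {
  stopifnot(label %in% c("favorable", "unfavorable"),
            length(channel_means) == 3L, length(channel_sds) == 3L,
            all(channel_means >= 0), all(channel_means <= 255),
            all(channel_sds >= 0), all(between_image_sds >= 0),
            smoothing_scale >= 0, streak_density >= 0,
            length(streak_brightness) == 3L,
            streak_length_range[1] >= 1L, streak_width_range[1] >= 1L,
            diff(streak_length_range) >= 0, diff(streak_width_range) >= 0)
  if (any(channel_means + 3 * channel_sds > 255 + 1e-9)) {
    stop("channel_means + 3 * channel_sds must stay within [0, 255]",
         call. = FALSE)
  }
  structure(list(label = label,
                 channel_means = as.numeric(channel_means),
                 channel_sds = as.numeric(channel_sds),
                 between_image_sds = as.numeric(between_image_sds),
                 smoothing_scale = as.numeric(smoothing_scale),
                 streak_density = as.numeric(streak_density),
                 streak_brightness = as.numeric(streak_brightness),
                 streak_length_range = as.integer(streak_length_range),
                 streak_width_range = as.integer(streak_width_range),
                 mean_offset = as.numeric(mean_offset)),
            class = "class_spec")
}

#' Default class specifications
#'
#' Channel means and between-image SDs equal the published group summary
#' values ([reference_group_summary()]). Within-image SDs were set so the
#' grayscale marginal reproduces the published white-percentage curve at
#' all four binarization thresholds; the unfavorable class carries a higher
#' streak density (more undecomposed straw). `mean_offset` values were
#' calibrated once by simulation so the composite means recover the target
#' channel means, and are frozen.
#'
#' @return A `class_spec`.
#' @export
favorable_spec <- function() {
  class_spec("favorable",
             channel_means = c(24.86, 19.62, 15.43),
             channel_sds = c(14, 12, 9),
             between_image_sds = c(2.78, 2.15, 1.81),
             smoothing_scale = 3,
             streak_density = 0.3,
             streak_brightness = c(150, 138, 105),
             mean_offset = c(-0.37, -0.40, -0.27))
}

#' @rdname favorable_spec
#' @export
unfavorable_spec <- function() {
  class_spec("unfavorable",
             channel_means = c(42.26, 30.39, 20.99),
             channel_sds = c(18, 16, 12),
             between_image_sds = c(4.30, 2.97, 2.16),
             smoothing_scale = 3,
             streak_density = 1.5,
             streak_brightness = c(170, 150, 110),
             mean_offset = c(-0.79, -0.87, -0.71))
}

# smoothed standard-normal field: white noise convolved with a Gaussian
# kernel (separable, edge-renormalized), then re-standardized to zero mean
# and unit sd so channel_sds apply exactly
smooth_field <- function(z, scale) {
  if (scale <= 0) return((z - mean(z)) / sd(z))
  r <- max(1L, ceiling(3 * scale))
  k <- exp(-((-r:r)^2) / (2 * scale^2))
  band <- function(n) {
    B <- matrix(0, n, n)
    for (d in -r:r) {
      idx <- seq_len(n - abs(d))
      B[cbind(idx + max(0, -d), idx + max(0, d))] <- k[d + r + 1L]
    }
    B / rowSums(B)
  }
  s <- band(nrow(z)) %*% z %*% t(band(ncol(z)))
  (s - mean(s)) / sd(s)
}

# stamp one bright elongated segment; returns linear cell indices
streak_cells <- function(h, w, cy, cx, theta, len, wid) {
  t <- seq(-len / 2, len / 2, by = 0.5)
  ys <- cy + t * sin(theta)
  xs <- cx + t * cos(theta)
  half <- (wid - 1) / 2
  dws <- if (half > 0) seq(-half, half, by = 0.5) else 0
  cells <- unlist(lapply(dws, function(dw) {
    py <- round(ys + dw * cos(theta))
    px <- round(xs - dw * sin(theta))
    keep <- py >= 1 & py <= h & px >= 1 & px <= w
    (px[keep] - 1) * h + py[keep]
  }))
  unique(cells)
}

#' Generate one synthetic compost-sample image
#'
#' Deterministic in (spec, dimensions, seed): the same call yields a
#' bit-identical image. Construction: shared smoothed-Gaussian luminance
#' field scaled by `channel_sds` around `channel_means + mean_offset +
#' jitter`; Poisson(`streak_density * H * W / 1e4`) bright streaks with
#' random position, orientation, length and width, alpha-blended at
#' `streak_brightness`; clamp to \[0, 255\] and round.
#'
#' @param spec a [class_spec()].
#' @param height,width image dimensions in pixels (both >= 16).
#' @param seed integer seed.
#' @return An [rgb_image()].
#' @export
generate_image <- function(spec, height, width, seed) {
  stopifnot(inherits(spec, "class_spec"))
  if (height < 16L || width < 16L) {
    stop("synthetic images must be at least 16 x 16", call. = FALSE)
  }
  px <- withr::with_seed(as.integer(seed), {
    field <- smooth_field(matrix(rnorm(height * width), height, width),
                          spec$smoothing_scale)
    jitter <- rnorm(1L) * spec$between_image_sds
    img <- array(0, dim = c(height, width, 3L))
    for (ch in 1:3) {
      img[, , ch] <- spec$channel_means[ch] + spec$mean_offset[ch] +
        jitter[ch] + spec$channel_sds[ch] * field
    }
    n_streaks <- rpois(1L, spec$streak_density * height * width / 1e4)
    if (n_streaks > 0) {
      for (s in seq_len(n_streaks)) {
        cy <- runif(1, 1, height); cx <- runif(1, 1, width)
        theta <- runif(1, 0, pi)
        len <- sample(spec$streak_length_range[1]:spec$streak_length_range[2], 1L)
        wid <- sample(spec$streak_width_range[1]:spec$streak_width_range[2], 1L)
        bright_mult <- runif(1, 0.75, 1.05)
        cells <- streak_cells(height, width, cy, cx, theta, len, wid)
        if (length(cells)) {
          for (ch in 1:3) {
            plane <- img[, , ch]
            plane[cells] <- 0.15 * plane[cells] +
              0.85 * spec$streak_brightness[ch] * bright_mult
            img[, , ch] <- plane
          }
        }
      }
    }
    img[img < 0] <- 0
    img[img > 255] <- 255
    round_half_up(img)
  })
  rgb_image(px, source_id = sprintf("synthetic_seed%d", as.integer(seed)),
            experiment_id = spec$label)
}

# splittable sub-seed: deterministic function of (master seed, experiment
# index, image index), kept below 2^31
derive_seed <- function(master, exp_index, img_index) {
  as.integer((abs(as.numeric(master)) * 48271 + exp_index * 69621 +
                img_index * 16807) %% 2147483647)
}

#' Generate a full synthetic composting study
#'
#' Mirrors the original study design: by default 3 favorable and 7
#' unfavorable experiments with 32 images each (320 images). Images are
#' written as PNG into one subdirectory per experiment; per-image sub-seeds
#' are derived deterministically from the master seed, so any subset is
#' reproducible independently and the same master seed reproduces the tree
#' bit-for-bit. A `groups.csv` and the generator configuration
#' (`generator.yml`) are written alongside.
#'
#' @param out_dir output directory (created if needed).
#' @param fav_spec,unfav_spec [class_spec()]s (defaults
#'   [favorable_spec()] / [unfavorable_spec()]).
#' @param images_per_experiment images per experiment (default 32).
#' @param fav_experiments,unfav_experiments experiment counts (default 3/7).
#' @param height,width image size (default 324 x 484).
#' @param seed master seed.
#' @return List with `dir`, `groups` (tibble), `files` (character vector).
#' @export
generate_study <- function(out_dir,
                           fav_spec = favorable_spec(),
                           unfav_spec = unfavorable_spec(),
                           images_per_experiment = 32L,
                           fav_experiments = 3L,
                           unfav_experiments = 7L,
                           height = 324L, width = 484L,
                           seed = 1L) {
  stopifnot(images_per_experiment >= 1L, fav_experiments >= 1L,
            unfav_experiments >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  specs <- c(rep(list(fav_spec), fav_experiments),
             rep(list(unfav_spec), unfav_experiments))
  exp_ids <- c(sprintf("FAV%02d", seq_len(fav_experiments)),
               sprintf("UNF%02d", seq_len(unfav_experiments)))
  files <- character(0)
  for (e in seq_along(specs)) {
    exp_dir <- file.path(out_dir, exp_ids[e])
    dir.create(exp_dir, showWarnings = FALSE)
    for (i in seq_len(images_per_experiment)) {
      img <- generate_image(specs[[e]], height, width,
                            seed = derive_seed(seed, e, i))
      f <- file.path(exp_dir, sprintf("img%03d.png", i))
      png::writePNG(img$pixels / 255, f)
      files <- c(files, f)
    }
  }
  groups <- tibble::tibble(
    experiment_id = exp_ids,
    label = c(rep("favorable", fav_experiments),
              rep("unfavorable", unfav_experiments)))
  write_groups(groups, file.path(out_dir, "groups.csv"))
  yaml::write_yaml(list(seed = as.integer(seed),
                        height = as.integer(height),
                        width = as.integer(width),
                        images_per_experiment = as.integer(images_per_experiment),
                        favorable = unclass(fav_spec),
                        unfavorable = unclass(unfav_spec)),
                   file.path(out_dir, "generator.yml"))
  list(dir = out_dir, groups = groups, files = files)
}
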