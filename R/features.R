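#' Extract the 17 color and texture parameters of one image
#'
#' Computes, in [compost_parameters()] order: channel means and medians of
#' the RGB components; mean and median of the weighted-luminance grayscale
#' conversion; white-pixel percentages after binarization at each
#' configured threshold; histogram entropy; and the four GLCM statistics
#' averaged over the directions 0/45/90/135 degrees.
#'
#' @param img an [rgb_image()].
#' @param config a [run_config()] (thresholds and GLCM settings are used).
#' @return Named numeric vector of length 17.
#' @export
#' @examples
#' img <- generate_image(favorable_spec(), 32, 32, seed = 1)
#' extract_features(img)
extract_features <- function(img, config = run_config()) {
  stopifnot(inherits(img, "rgb_image"), inherits(config, "run_config"))
  gs <- to_grayscale(img)
  wh <- vapply(config$thresholds,
               function(t) white_percentage(binarize(gs, t)), numeric(1))
  names(wh) <- paste0("WH_PERCENT", seq_along(wh))
  out <- c(channel_stats(img), grayscale_stats(gs), wh,
           texture_vector(gs, levels = config$glcm_levels,
                          quantization = config$glcm_quantization))
  if (identical(config$thresholds, c(0.05, 0.10, 0.15, 0.20))) {
    stopifnot(identical(names(out), compost_parameters()))
  }
  out
}

#' Extract features for every image under a study directory
#'
#' Walks `image_root`, treating each immediate subdirectory as one
#' composting experiment (its name becomes `experiment_id`) and every
#' decodable JPEG/PNG/TIFF inside as one sample image. Corrupt files are
#' skipped with a warning and counted; rows are sorted by
#' (`experiment_id`, `source_id`) so the output is independent of directory
#' enumeration order.
#'
#' @param image_root directory containing one subdirectory per experiment.
#' @param config a [run_config()].
#' @param quiet suppress progress messages (default TRUE).
#' @return Feature table tibble (`experiment_id`, `source_id`, 17 parameter
#'   columns) with attribute `n_skipped` (count of undecodable files).
#' @export
extract_features_dir <- function(image_root, config = run_config(),
                                 quiet = TRUE) {
  if (!dir.exists(image_root)) {
    stop("image root does not exist: ", image_root, call. = FALSE)
  }
  exts <- "\\.(png|jpe?g|tiff?)$"
  dirs <- list.dirs(image_root, recursive = FALSE)
  files <- unlist(lapply(dirs, list.files, pattern = exts,
                         ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    stop("no images found under ", image_root,
         " (expected experiment subdirectories with png/jpeg/tiff files)",
         call. = FALSE)
  }
  n_skipped <- 0L
  rows <- lapply(files, function(f) {
    img <- tryCatch(read_image(f), error = function(e) {
      warning("skipping ", f, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(img)) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    fv <- extract_features(img, config)
    tibble::tibble(experiment_id = img$experiment_id,
                   source_id = img$source_id, !!!as.list(fv))
  })
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) == 0L) {
    stop("no image under ", image_root, " could be decoded", call. = FALSE)
  }
  tbl <- dplyr::arrange(tbl, .data$experiment_id, .data$source_id)
  if (!quiet) {
    message(sprintf("extracted features for %d images (%d skipped) from %d experiments",
                    nrow(tbl), n_skipped, length(unique(tbl$experiment_id))))
  }
  tbl <- validate_feature_table(tbl)
  attr(tbl, "n_skipped") <- n_skipped
  tbl
}
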