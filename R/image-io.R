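#' Construct an RGB image object
#'
#' The raw analysis input: an H x W grid of 3-channel 8-bit pixels with two
#' identifying labels. Values are validated to be integers in \[0, 255\] and
#' the grid must be at least 2 x 2 so that co-occurrence matrices have at
#' least one neighbor pair in every analyzed direction.
#'
#' @param pixels numeric or integer H x W x 3 array (channels R, G, B).
#' @param source_id text label for the image (typically the file stem).
#' @param experiment_id text label for the composting experiment the image
#'   belongs to (e.g. a chamber name).
#' @return An object of class `rgb_image`: a list with elements `pixels`
#'   (integer array), `source_id`, `experiment_id`.
#' @export
rgb_image <- function(pixels, source_id = "unknown", experiment_id = "unknown") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  d <- dim(pixels)
  if (d[1] < 2L || d[2] < 2L) {
    stop("image must be at least 2 x 2 pixels (got ",
         d[1], " x ", d[2], ")", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255) ||
      any(pixels != round(pixels))) {
    stop("channel values must be integers in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels,
                 source_id = as.character(source_id),
                 experiment_id = as.character(experiment_id)),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d px  experiment=%s  source=%s\n",
              d[1], d[2], x$experiment_id, x$source_id))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

#' Read a sample image from disk
#'
#' Decodes JPEG, PNG or baseline TIFF into an [rgb_image()]. Grayscale
#' images on disk are replicated across the three channels; alpha channels
#' are dropped. Bit depths other than 8 are linearly rescaled to \[0, 255\]
#' (16-bit values are divided by 257 and rounded), so synthetic fixtures of
#' any depth are usable. No denoising or color correction is applied:
#' features are computed on the decoded pixels as stored.
#'
#' @param path path to a `.png`, `.jpg`/`.jpeg`, or `.tif`/`.tiff` file.
#' @param experiment_id experiment label to attach; defaults to the name of
#'   the parent directory, matching a layout of one directory per
#'   composting experiment.
#' @return An [rgb_image()].
#' @export
read_image <- function(path, experiment_id = basename(dirname(normalizePath(path, mustWork = FALSE)))) {
  if (!file.exists(path)) {
    stop("image file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      tif  = ,
      tiff = read_tiff(path),
      stop("unsupported image extension '", ext, "'", call. = FALSE)
    ),
    error = function(e) {
      stop("failed to decode image ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  # readPNG/readJPEG return doubles in [0, 1] (already depth-normalized);
  # read_tiff returns the same convention.
  if (length(dim(arr)) == 2L) {
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  } else if (dim(arr)[3] == 2L) {        # gray + alpha
    arr <- array(rep(arr[, , 1L], 3L), dim = c(dim(arr)[1:2], 3L))
  } else if (dim(arr)[3] >= 4L) {        # drop alpha
    arr <- arr[, , 1:3, drop = FALSE]
  } else if (dim(arr)[3] == 1L) {
    arr <- array(rep(arr[, , 1L], 3L), dim = c(dim(arr)[1:2], 3L))
  }
  px <- round_half_up(arr * 255)
  rgb_image(px,
            source_id = tools::file_path_sans_ext(basename(path)),
            experiment_id = experiment_id)
}

#' Write a feature table to CSV
#'
#' One row per image: `experiment_id`, `source_id`, then the 17 parameters
#' in [compost_parameters()] order. Values are serialized with full double
#' precision (well beyond 6 significant digits), so a write/read round trip
#' reproduces the table.
#'
#' @param table tibble/data.frame with columns `experiment_id`, `source_id`
#'   and the 17 parameter columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- validate_feature_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A validated feature table tibble.
#' @export
read_feature_table <- function(path) {
  cols <- readr::cols(
    experiment_id = readr::col_character(),
    source_id = readr::col_character(),
    .default = readr::col_double()
  )
  tbl <- readr::read_csv(path, col_types = cols, progress = FALSE)
  validate_feature_table(tbl)
}

validate_feature_table <- function(table) {
  expected <- c("experiment_id", "source_id", compost_parameters())
  if (!all(expected %in% names(table))) {
    stop("feature table is missing columns: ",
         paste(setdiff(expected, names(table)), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) == 0L) {
    stop("feature table is empty", call. = FALSE)
  }
  key <- paste(table$experiment_id, table$source_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (experiment_id, source_id) pairs in feature table",
         call. = FALSE)
  }
  tibble::as_tibble(table[, expected])
}

#' Read a group-assignment table
#'
#' CSV with columns `experiment_id,label`, labels in
#' `{favorable, unfavorable}`; both labels must be represented.
#'
#' @param path CSV path.
#' @return Tibble with columns `experiment_id`, `label`.
#' @export
read_groups <- function(path) {
  tbl <- readr::read_csv(path,
                         col_types = readr::cols(
                           experiment_id = readr::col_character(),
                           label = readr::col_character()),
                         progress = FALSE)
  validate_groups(tbl)
}

#' Write a group-assignment table
#' @param groups tibble with columns `experiment_id`, `label`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  groups <- validate_groups(groups)
  readr::write_csv(groups, path)
  invisible(path)
}

validate_groups <- function(groups) {
  if (!all(c("experiment_id", "label") %in% names(groups))) {
    stop("groups table needs columns experiment_id, label", call. = FALSE)
  }
  bad <- setdiff(unique(groups$label), c("favorable", "unfavorable"))
  if (length(bad)) {
    stop("unknown group labels: ", paste(bad, collapse = ", "),
         " (expected favorable/unfavorable)", call. = FALSE)
  }
  for (lbl in c("favorable", "unfavorable")) {
    if (!any(groups$label == lbl)) {
      stop("group label '", lbl, "' has no experiments", call. = FALSE)
    }
  }
  if (anyDuplicated(groups$experiment_id)) {
    stop("duplicate experiment_id in groups table", call. = FALSE)
  }
  tibble::as_tibble(groups[, c("experiment_id", "label")])
}
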