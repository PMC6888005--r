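#' Pipeline run configuration
#'
#' Bundles the tunable settings of the analysis: binarization thresholds,
#' GLCM quantization, the significance level of the group test, and the
#' master seed. Defaults reproduce the published analysis settings.
#'
#' @param thresholds strictly increasing binarization thresholds in (0, 1);
#'   default `c(0.05, 0.10, 0.15, 0.20)` (the white-percentage parameters
#'   WH_PERCENT1..4 correspond to these in order).
#' @param glcm_levels brightness classes for the co-occurrence matrices
#'   (default 8).
#' @param glcm_quantization `"fixed"` (bins over \[0, 255\], default) or
#'   `"min_max"` (per-image stretch, for sensitivity checks only).
#' @param alpha significance level for the Mann-Whitney U test (default 0.05).
#' @param seed master seed for synthetic data generation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(thresholds = c(0.05, 0.10, 0.15, 0.20),
                       glcm_levels = 8L,
                       glcm_quantization = c("fixed", "min_max"),
                       alpha = 0.05,
                       seed = 1L) {
  glcm_quantization <- match.arg(glcm_quantization)
  if (length(thresholds) < 1L || any(thresholds <= 0) || any(thresholds >= 1) ||
      is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing values in (0, 1)",
         call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (glcm_levels < 2L) stop("glcm_levels must be >= 2", call. = FALSE)
  structure(list(thresholds = as.numeric(thresholds),
                 glcm_levels = as.integer(glcm_levels),
                 glcm_quantization = glcm_quantization,
                 alpha = as.numeric(alpha),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read/write a run configuration as YAML
#' @param path YAML file path.
#' @return [run_config()] for `read_run_config`; `path` invisibly for
#'   `write_run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
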