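#' Absolute percentage difference relative to the favorable group
#'
#' `100 * |mean_unfav - mean_fav| / mean_fav`; `NA` when `mean_fav` is 0.
#' Invariant under common rescaling of both means.
#'
#' @param mean_fav favorable-group mean(s).
#' @param mean_unfav unfavorable-group mean(s).
#' @return Non-negative percentage(s), `NA` where `mean_fav == 0`.
#' @export
#' @examples
#' pct_diff(19.33, 37.07)  # 91.77 -> prints as 92%
pct_diff <- function(mean_fav, mean_unfav) {
  out <- 100 * abs(mean_unfav - mean_fav) / mean_fav
  out[mean_fav == 0] <- NA_real_
  out
}

#' Mann-Whitney U test for two independent samples
#'
#' Rank-based two-sided test. Mid-ranks are assigned to ties;
#' `U = min(U_x, U_y)`. For pooled sample sizes up to `exact_limit` the
#' p-value is computed by exact enumeration of all assignments of the
#' pooled values to the two groups (valid under ties); for larger samples
#' the normal approximation with tie correction and continuity correction
#' is used.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param method `"auto"` (default: exact iff pooled size <= `exact_limit`),
#'   `"exact"`, or `"asymptotic"`.
#' @param exact_limit pooled-size cutoff for the exact mode (default 20).
#' @return List with `U`, `p_value`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney_u <- function(x, y, method = c("auto", "exact", "asymptotic"),
                           exact_limit = 20L) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L || anyNA(c(x, y))) {
    stop("x and y must be non-empty numeric vectors without NA",
         call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))                       # mid-ranks under ties
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  if (method == "auto") method <- if (n <= exact_limit) "exact" else "asymptotic"

  if (method == "exact") {
    # enumerate all choose(n, n1) group assignments of the pooled values;
    # two-sided p = share of assignments at least as extreme (|U1 - mean|)
    t_obs <- abs(U1 - n1 * n2 / 2)
    idx <- utils::combn(n, n1)
    R1 <- colSums(matrix(r[idx], nrow = n1))
    t_all <- abs(R1 - n1 * (n1 + 1) / 2 - n1 * n2 / 2)
    p <- mean(t_all >= t_obs - 1e-9)
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1                                # all values identical
    } else {
      z <- (U - n1 * n2 / 2 + 0.5) / sqrt(sigma2)   # continuity correction
      p <- min(1, 2 * pnorm(z))
    }
  }
  list(U = U, p_value = p, method = method)
}

#' Compare the favorable and unfavorable groups on all 17 parameters
#'
#' The unit of analysis is the image: for each parameter the arithmetic
#' mean and sample standard deviation (n - 1 denominator) are computed over
#' all images of each group, the two-sided Mann-Whitney U test compares the
#' per-image values between groups, and the absolute percentage difference
#' [pct_diff()] summarizes the effect relative to the favorable mean.
#' Experiment-level clustering is deliberately ignored and no
#' multiple-testing correction is applied, mirroring the original analysis;
#' both are documented limitations.
#'
#' @param table feature table (from [extract_features_dir()] or
#'   [read_feature_table()]).
#' @param groups group assignment tibble (`experiment_id`, `label` in
#'   favorable/unfavorable), e.g. from [read_groups()].
#' @param config a [run_config()] (supplies `alpha`, echoed in reports).
#' @return An object of class `group_comparison`: list with `table` (one
#'   row per parameter: `parameter`, `mean_fav`, `sd_fav`, `mean_unfav`,
#'   `sd_unfav`, `p_value`, `pct_diff`), `n_fav`, `n_unfav`, `alpha`,
#'   `config`.
#' @export
summarize_groups <- function(table, groups, config = run_config()) {
  table <- validate_feature_table(table)
  groups <- validate_groups(groups)
  unknown <- setdiff(unique(table$experiment_id), groups$experiment_id)
  if (length(unknown)) {
    stop("experiments missing from the group assignment: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lab <- groups$label[match(table$experiment_id, groups$experiment_id)]
  fav <- table[lab == "favorable", , drop = FALSE]
  unf <- table[lab == "unfavorable", , drop = FALSE]
  if (nrow(fav) < 2L || nrow(unf) < 2L) {
    stop("each group needs at least 2 images (favorable: ", nrow(fav),
         ", unfavorable: ", nrow(unf), ")", call. = FALSE)
  }
  params <- compost_parameters()
  rows <- lapply(params, function(p) {
    xf <- fav[[p]]; xu <- unf[[p]]
    mw <- mann_whitney_u(xf, xu)
    tibble::tibble(parameter = p,
                   mean_fav = mean(xf), sd_fav = sd(xf),
                   mean_unfav = mean(xu), sd_unfav = sd(xu),
                   p_value = mw$p_value,
                   pct_diff = pct_diff(mean(xf), mean(xu)))
  })
  structure(list(table = dplyr::bind_rows(rows),
                 n_fav = nrow(fav), n_unfav = nrow(unf),
                 alpha = config$alpha, config = config),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d favorable vs %d unfavorable images, alpha = %g\n",
              x$n_fav, x$n_unfav, x$alpha))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' Count parameters whose percentage difference exceeds thresholds
#'
#' For each threshold, the number of parameters with `pct_diff` strictly
#' greater than it; `NA` differences never count. Non-increasing in the
#' threshold.
#'
#' @param comparison a `group_comparison` from [summarize_groups()], or a
#'   data frame with a `pct_diff` column covering all 17 parameters.
#' @param thresholds percentages (default `c(10, 50, 100)`).
#' @return Named integer vector, one count per threshold.
#' @export
threshold_counts <- function(comparison, thresholds = c(10, 50, 100)) {
  tbl <- if (inherits(comparison, "group_comparison")) comparison$table
         else comparison
  if (!"pct_diff" %in% names(tbl) || nrow(tbl) < length(compost_parameters())) {
    stop("comparison must cover all 17 parameters with a pct_diff column",
         call. = FALSE)
  }
  counts <- vapply(thresholds,
                   function(t) sum(tbl$pct_diff > t, na.rm = TRUE),
                   numeric(1))
  stats::setNames(as.integer(counts), paste0(">", thresholds, "%"))
}

#' Render a group comparison as a JSON report and text table
#'
#' Display rounding follows the published convention: group means and SDs
#' to 2 decimals, percentage differences to the nearest integer percent
#' (half up), p-values printed as `<0.001` when below 0.001. The JSON
#' report also carries the unrounded values, the threshold counts
#' (10/50/100%) and the full resolved configuration for provenance.
#'
#' @param comparison a `group_comparison` from [summarize_groups()].
#' @param json_path optional path for the JSON report.
#' @param text_path optional path for the plain-text summary table.
#' @return The report list, invisibly.
#' @export
render_report <- function(comparison, json_path = NULL, text_path = NULL) {
  if (!inherits(comparison, "group_comparison")) {
    stop("`comparison` must come from summarize_groups()", call. = FALSE)
  }
  tbl <- comparison$table
  if (nrow(tbl) == 0L) stop("comparison has no parameters", call. = FALSE)
  counts <- threshold_counts(comparison)
  disp <- tibble::tibble(
    parameter = tbl$parameter,
    mean_fav = round(tbl$mean_fav, 2), sd_fav = round(tbl$sd_fav, 2),
    mean_unfav = round(tbl$mean_unfav, 2), sd_unfav = round(tbl$sd_unfav, 2),
    p_display = ifelse(tbl$p_value < 0.001, "<0.001",
                       sprintf("%.3f", tbl$p_value)),
    pct_diff_display = ifelse(is.na(tbl$pct_diff), NA,
                              round_half_up(tbl$pct_diff))
  )
  report <- list(
    n_fav = comparison$n_fav,
    n_unfav = comparison$n_unfav,
    alpha = comparison$alpha,
    parameters = tbl,
    display = disp,
    threshold_counts = as.list(counts),
    config = unclass(comparison$config)
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  if (!is.null(text_path)) {
    hdr <- sprintf("%-13s %10s %8s %10s %8s %8s %6s",
                   "Parameter", "Fav.mean", "Fav.SD", "Unf.mean", "Unf.SD",
                   "p-value", "Diff%")
    lines <- sprintf("%-13s %10.2f %8.2f %10.2f %8.2f %8s %6s",
                     disp$parameter, disp$mean_fav, disp$sd_fav,
                     disp$mean_unfav, disp$sd_unfav, disp$p_display,
                     ifelse(is.na(disp$pct_diff_display), "NA",
                            as.character(disp$pct_diff_display)))
    foot <- sprintf("Parameters with |diff| > 10/50/100%%: %d / %d / %d  (n = %d fav, %d unfav)",
                    counts[1], counts[2], counts[3],
                    comparison$n_fav, comparison$n_unfav)
    writeLines(c(hdr, lines, "", foot), text_path)
  }
  invisible(report)
}
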