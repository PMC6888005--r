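test_that("pct_diff hand values and invariances", {
  expect_equal(pct_diff(19.33, 37.07), 91.77, tolerance = 1e-3)
  expect_equal(pct_diff(10, 15), 50)
  expect_equal(pct_diff(10, 10), 0)
  expect_equal(pct_diff(0.62, 0.38), pct_diff(62, 38))   # scale invariance
  expect_true(is.na(pct_diff(0, 5)))
  set.seed(10)
  a <- runif(20, 1, 9); b <- runif(20, 1, 9); k <- runif(20, 0.1, 10)
  expect_equal(pct_diff(k * a, k * b), pct_diff(a, b))
})

test_that("Mann-Whitney hand example and exchangeability limit", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 1 / 3)
  expect_identical(mw$method, "exact")
  # identical pooled values -> no assignment is more extreme than observed
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5))$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney is symmetric in its arguments", {
  set.seed(11)
  for (rep in 1:10) {
    x <- sample(0:20, 6, replace = TRUE)   # ties likely
    y <- sample(0:20, 9, replace = TRUE)
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$U, b$U)
    expect_equal(a$p_value, b$p_value)
  }
  x <- rnorm(30); y <- rnorm(25)
  a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
  expect_equal(a$U, b$U)
  expect_equal(a$p_value, b$p_value)
})

test_that("exact p-values match the full permutation oracle (with ties)", {
  set.seed(12)
  for (rep in 1:12) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(0:6, n1, replace = TRUE)   # heavy ties on purpose
    y <- sample(0:6, n2, replace = TRUE)
    expect_equal(mann_whitney_u(x, y, method = "exact")$p_value,
                 oracle_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("asymptotic mode agrees with exact near the cutoff and with wilcox.test", {
  set.seed(13)
  for (rep in 1:8) {
    x <- rnorm(10); y <- rnorm(10, mean = runif(1, 0, 1.5))  # no ties a.s.
    ex <- mann_whitney_u(x, y, method = "exact")$p_value
    as <- mann_whitney_u(x, y, method = "asymptotic")$p_value
    expect_lt(abs(ex - as), 0.01)
  }
  # independent reference implementation, tie-corrected normal approximation
  set.seed(14)
  x <- sample(0:30, 25, replace = TRUE); y <- sample(5:35, 30, replace = TRUE)
  ours <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                             exact = FALSE))
  expect_identical(ours$method, "asymptotic")
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("summarize_groups computes group means, SDs and differences", {
  set.seed(15)
  tbl <- random_feature_table(4, 3)  # EXP1..EXP4
  groups <- tibble::tibble(
    experiment_id = sprintf("EXP%d", 1:4),
    label = c("favorable", "favorable", "unfavorable", "unfavorable"))
  cmp <- summarize_groups(tbl, groups)
  expect_s3_class(cmp, "group_comparison")
  expect_identical(cmp$table$parameter, compost_parameters())
  expect_identical(c(cmp$n_fav, cmp$n_unfav), c(6L, 6L))
  # spot-check one parameter against direct arithmetic
  fav_vals <- tbl$R_MEAN[tbl$experiment_id %in% c("EXP1", "EXP2")]
  unf_vals <- tbl$R_MEAN[tbl$experiment_id %in% c("EXP3", "EXP4")]
  row <- cmp$table[cmp$table$parameter == "R_MEAN", ]
  expect_equal(row$mean_fav, mean(fav_vals))
  expect_equal(row$sd_fav, sd(fav_vals))            # n - 1 denominator
  expect_equal(row$pct_diff,
               100 * abs(mean(unf_vals) - mean(fav_vals)) / mean(fav_vals))
  expect_true(all(cmp$table$sd_fav >= 0 & cmp$table$sd_unfav >= 0))
})

test_that("identical groups give zero differences and p near 1", {
  set.seed(16)
  half <- random_feature_table(1, 4)
  other <- dplyr::mutate(half, experiment_id = "EXP2")
  tbl <- dplyr::bind_rows(half, other)
  groups <- tibble::tibble(experiment_id = c("EXP1", "EXP2"),
                           label = c("favorable", "unfavorable"))
  cmp <- summarize_groups(tbl, groups)
  expect_true(all(cmp$table$pct_diff == 0))
  expect_true(all(cmp$table$p_value == 1))
})

test_that("summarize_groups validates its inputs", {
  set.seed(17)
  tbl <- random_feature_table(3, 2)
  groups <- tibble::tibble(experiment_id = c("EXP1", "EXP2"),
                           label = c("favorable", "unfavorable"))
  expect_error(summarize_groups(tbl, groups), "EXP3")
})

test_that("threshold counts are correct and monotone", {
  fake <- function(pd) {
    structure(list(table = tibble::tibble(parameter = compost_parameters(),
                                          pct_diff = pd)),
              class = "group_comparison")
  }
  expect_identical(unname(threshold_counts(fake(rep(0, 17)))), c(0L, 0L, 0L))
  expect_identical(unname(threshold_counts(fake(rep(60, 17)))), c(17L, 17L, 0L))
  set.seed(18)
  for (rep in 1:10) {
    counts <- threshold_counts(fake(runif(17, 0, 200)),
                               thresholds = c(5, 20, 80, 150))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("render_report applies display rounding and writes both outputs", {
  set.seed(19)
  tbl <- random_feature_table(2, 3)
  groups <- tibble::tibble(experiment_id = c("EXP1", "EXP2"),
                           label = c("favorable", "unfavorable"))
  cmp <- summarize_groups(tbl, groups)
  cmp$table$pct_diff[1] <- 91.77            # known rounding case
  cmp$table$pct_diff[2] <- 12.5             # half rounds up
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "report.json"); tp <- file.path(dir, "report.txt")
  rep_out <- render_report(cmp, json_path = jp, text_path = tp)
  expect_equal(rep_out$display$pct_diff_display[1], 92)
  expect_equal(rep_out$display$pct_diff_display[2], 13)
  parsed <- jsonlite::read_json(jp)
  expect_length(parsed$parameters, 17)
  expect_identical(parsed$parameters[[1]]$parameter, "R_MEAN")
  expect_true(all(c("threshold_counts", "config") %in% names(parsed)))
  txt <- readLines(tp)
  expect_length(txt, 17 + 3)                # header + rows + blank + footer
  # empty comparison is rejected before any file is written
  empty <- cmp; empty$table <- cmp$table[0, ]
  expect_error(render_report(empty, json_path = file.path(dir, "no.json")),
               "no parameters")
  expect_false(file.exists(file.path(dir, "no.json")))
})
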