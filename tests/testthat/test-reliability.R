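make_table <- function(rows) {
  reader_table(dplyr::bind_rows(rows))
}

# long-format rows for one (patient, reader, method) cell
cell <- function(patient, reader, method, ctrl, btv) {
  tibble::tibble(patient_id = patient, reader_id = reader,
                 `repeat` = seq_along(ctrl), method = method,
                 ctrl_suv_mean = ctrl, btv_cm3 = btv)
}

test_that("cov_percent follows the sd/mean definition", {
  expect_equal(cov_percent(rep(5, 6)), 0)
  expect_equal(cov_percent(c(1, 2, 3)), 50)  # sd 1, mean 2
  # scale invariance
  set.seed(4)
  v <- runif(10, 1, 5)
  expect_equal(cov_percent(v * 17.3), cov_percent(v))
  expect_error(cov_percent(1), "at least 2")
  expect_error(cov_percent(c(-2, 2)), "positive")
})

test_that("intra-reader CoV is computed per (patient, reader) cell", {
  tab <- make_table(list(
    cell("p1", "r1", "MI", c(1, 2, 3), c(5, 5, 5)),
    cell("p2", "r1", "MI", c(2, 2, 2), c(4, 4, 4))))
  covs <- intra_reader_cov(tab, "ctrl_suv_mean", "MI")
  expect_equal(sort(covs$cov_percent), c(0, 50))
  expect_equal(median(covs$cov_percent), 25)
  # identical repeats in every cell -> all CoVs zero, median 0
  covs_btv <- intra_reader_cov(tab, "btv_cm3", "MI")
  expect_true(all(covs_btv$cov_percent == 0))

  # incomplete repeat set names the offending cell
  bad <- dplyr::bind_rows(tab, cell("p3", "r1", "MI", c(1, 1), c(1, 1)))
  expect_error(intra_reader_cov(reader_table(bad), "ctrl_suv_mean", "MI"),
               "incomplete repeat set for patient p3")
  expect_error(make_table(list()), "empty|missing")
})

test_that("inter-reader CoV averages repeats before pooling readers", {
  rows <- purrr::imap(c(r1 = 2, r2 = 2, r3 = 2, r4 = 4), function(m, r)
    cell("p1", r, "MI", rep(m, 6), rep(1, 6)))
  tab <- make_table(rows)
  out <- inter_reader_cov(tab, "ctrl_suv_mean", "MI")
  expect_equal(out$cov_percent, 40)  # sd 1, mean 2.5

  # scale invariance of the pooled statistic
  tab2 <- dplyr::mutate(tab, ctrl_suv_mean = ctrl_suv_mean * 3)
  expect_equal(inter_reader_cov(tab2, "ctrl_suv_mean", "MI")$cov_percent, 40)

  solo <- make_table(list(cell("p9", "r1", "MI", c(1, 1), c(1, 1))))
  expect_error(inter_reader_cov(solo, "ctrl_suv_mean", "MI"), "only 1 reader")
})

test_that("ICC(2,1) matches an independent ANOVA oracle to 1e-10", {
  set.seed(11)
  m <- matrix(rnorm(24, 10, 2), 6, 4)
  m[, 2] <- m[, 2] + rnorm(6, 0, 1)
  r <- icc_2_1(m)
  expect_equal(r$icc, icc_oracle(m), tolerance = 1e-10)
  # frozen CI from an external two-way random-effects single-measurement
  # absolute-agreement implementation (cross-validated once)
  expect_equal(round(r$ci_low, 2), -0.33)
  expect_equal(round(r$ci_high, 2), 0.42)

  # property sweep: random sizes, scales and rater biases
  set.seed(77)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    k <- sample(2:8, 1)
    mm <- matrix(rnorm(n * k, 50, 10), n, k) +
      matrix(rep(rnorm(k, 0, 3), each = n), n, k)
    expect_equal(icc_2_1(mm)$icc, icc_oracle(mm), tolerance = 1e-10)
  }
})

test_that("ICC handles perfect agreement, bands and degenerate input", {
  base <- matrix(rep(c(3, 7, 1, 9, 5), 2), 5, 2)
  perfect <- icc_2_1(base)
  expect_equal(perfect$icc, 1.0)
  expect_equal(perfect$interpretation, "excellent")

  expect_error(icc_2_1(matrix(2, 4, 3)), "constant")
  expect_error(icc_2_1(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
  expect_error(icc_2_1(matrix(1:3, 3, 1)), "at least 2")

  expect_equal(icc_2_1(matrix(c(1, 2, 3, 3, 2, 1), 3, 2))$interpretation,
               "poor")
  ci <- icc_2_1(base + matrix(rnorm(10, 0, 0.1), 5, 2))
  expect_lte(ci$ci_low, ci$icc)
  expect_gte(ci$ci_high, ci$icc)
  expect_s3_class(tidy(ci), "tbl_df")
})

test_that("reliability report assembles the median (range) study layout", {
  set.seed(31)
  rows <- list()
  for (p in c("p1", "p2", "p3")) {
    for (r in c("r1", "r2")) {
      mu <- runif(1, 0.9, 1.1)
      rows <- c(rows, list(
        cell(p, r, "MI", rep(mu, 6), rep(4, 6)),
        cell(p, r, "gCS", mu * (1 + abs(rnorm(6, 0, 0.03))),
             4 * (1 + abs(rnorm(6, 0, 0.08))))))
    }
  }
  tab <- make_table(rows)
  rep <- reliability_report(tab)

  mi_overall <- dplyr::filter(rep$intra_summary, group == "overall",
                              parameter == "ctrl_suv_mean", method == "MI")
  gcs_overall <- dplyr::filter(rep$intra_summary, group == "overall",
                               parameter == "ctrl_suv_mean", method == "gCS")
  expect_equal(mi_overall$median, 0)
  expect_gt(gcs_overall$median, 0)

  expect_true(all(c("icc", "comparisons") %in% names(rep)))
  expect_equal(nrow(dplyr::filter(rep$icc, method == "MI",
                                  parameter == "ctrl_suv_mean")), 1)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_output(print(rep), "intra-reader CoV")

  # CSV round trip of the reader table
  dir <- withr::local_tempdir()
  p <- file.path(dir, "table.csv")
  write_reader_table(tab, p)
  back <- read_reader_table(p)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$ctrl_suv_mean, tab$ctrl_suv_mean)
})

test_that("method comparison surfaces Wilcoxon and Mann-Whitney p-values", {
  set.seed(13)
  rows <- list()
  for (p in paste0("p", 1:6)) {
    for (r in c("r1", "r2", "r3")) {
      rows <- c(rows, list(
        cell(p, r, "MI", rep(1, 6), rep(4, 6)),
        cell(p, r, "gCS", 1 + abs(rnorm(6, 0, 0.05)),
             4 + abs(rnorm(6, 0, 0.3)))))
    }
  }
  cmp <- compare_methods(make_table(rows), "ctrl_suv_mean")
  overall <- dplyr::filter(cmp, group == "overall", level == "intra-reader")
  expect_equal(overall$test, "mann-whitney-u")
  expect_lt(overall$p_value, 0.05)  # gCS variability strictly dominates
  expect_true(all(c("intra-reader", "inter-reader") %in% cmp$level))
})
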