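#' Coefficient of variation in percent
#'
#' `100 * sd(values) / mean(values)`, with the sample (n-1) standard
#' deviation. This is the dispersion measure used for both intra-reader
#' (over repeats) and inter-reader (over reader means) variability.
#'
#' @param values Numeric vector, at least 2 values, positive mean.
#' @return CoV in percent.
#' @export
cov_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("CoV needs at least 2 values, got ", length(values))
  if (anyNA(values) || any(!is.finite(values)))
    stop("CoV inputs must be finite")
  m <- mean(values)
  if (m <= 0) stop("CoV undefined: mean must be positive, got ", m)
  100 * sd(values) / m
}

reader_table_cols <- c("patient_id", "reader_id", "repeat", "method",
                       "ctrl_suv_mean", "btv_cm3")

#' Validate a reader-study measurement table
#'
#' The long-format table feeding the reliability statistics: one row per
#' (patient, reader, repeat, method) with the extracted background
#' `ctrl_suv_mean` and `btv_cm3`. Repeat indices must be unique within each
#' (patient, reader, method) cell and measurements finite and non-negative.
#'
#' @param table A data frame with columns `patient_id`, `reader_id`,
#'   `repeat`, `method` (`"MI"` or `"gCS"`), `ctrl_suv_mean`, `btv_cm3`.
#' @return The table as a tibble, invisibly checked.
#' @export
reader_table <- function(table) {
  table <- tibble::as_tibble(table)
  missing_cols <- setdiff(reader_table_cols, names(table))
  if (length(missing_cols))
    stop("reader table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(table) == 0L) stop("reader table is empty")
  if (!all(table$method %in% c("MI", "gCS")))
    stop("method must be 'MI' or 'gCS'")
  vals <- c(table$ctrl_suv_mean, table$btv_cm3)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals < 0))
    stop("measurements must be finite and non-negative")
  dup <- table |>
    dplyr::count(.data$patient_id, .data$reader_id, .data$method,
                 .data$`repeat`) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup))
    stop("duplicate repeat indices, e.g. patient ", dup$patient_id[1],
         " reader ", dup$reader_id[1], " repeat ", dup$`repeat`[1])
  table
}

#' Read / write a reader table as CSV
#'
#' @param path CSV path with the columns documented in [reader_table()].
#' @return A validated tibble.
#' @export
read_reader_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  reader_table(read.csv(path, check.names = FALSE))
}

#' @rdname read_reader_table
#' @param table A [reader_table()].
#' @export
write_reader_table <- function(table, path) {
  table <- reader_table(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

check_param <- function(parameter) {
  if (!parameter %in% c("ctrl_suv_mean", "btv_cm3"))
    stop("`parameter` must be 'ctrl_suv_mean' or 'btv_cm3'")
  parameter
}

method_subset <- function(table, method) {
  table <- reader_table(table)
  if (!method %in% table$method)
    stop("no rows for method '", method, "'")
  dplyr::filter(table, .data$method == !!method)
}

#' Intra-reader coefficient of variation
#'
#' One CoV per (patient, reader) cell, computed over that reader's repeated
#' measurements of the chosen parameter. Every cell must carry the full
#' repeat set (the maximum repeat count present for the method); an
#' incomplete cell is an error naming it.
#'
#' @param table A [reader_table()].
#' @param parameter `"ctrl_suv_mean"` or `"btv_cm3"`.
#' @param method `"MI"` or `"gCS"`.
#' @return A tibble with columns `patient_id`, `reader_id`, `cov_percent`.
#' @seealso [summarise_cov()] for the median (range) layout per reader and
#'   overall.
#' @export
intra_reader_cov <- function(table, parameter, method) {
  check_param(parameter)
  tab <- method_subset(table, method)
  counts <- dplyr::count(tab, .data$patient_id, .data$reader_id)
  full <- max(counts$n)
  bad <- dplyr::filter(counts, .data$n < full)
  if (nrow(bad))
    stop("incomplete repeat set for patient ", bad$patient_id[1],
         ", reader ", bad$reader_id[1], ": ", bad$n[1], " of ", full,
         " repeats")
  if (full < 2L) stop("need at least 2 repeats per cell")
  tab |>
    dplyr::group_by(.data$patient_id, .data$reader_id) |>
    dplyr::summarise(cov_percent = cov_percent(.data[[parameter]]),
                     .groups = "drop")
}

#' Inter-reader coefficient of variation
#'
#' Per patient: each reader's measurements are first averaged over repeats,
#' then the CoV is taken across the reader means. Patients seen by fewer
#' than two readers are an error.
#'
#' @inheritParams intra_reader_cov
#' @return A tibble with columns `patient_id`, `cov_percent`.
#' @export
inter_reader_cov <- function(table, parameter, method) {
  check_param(parameter)
  tab <- method_subset(table, method)
  means <- tab |>
    dplyr::group_by(.data$patient_id, .data$reader_id) |>
    dplyr::summarise(value = mean(.data[[parameter]]), .groups = "drop")
  counts <- dplyr::count(means, .data$patient_id)
  bad <- dplyr::filter(counts, .data$n < 2L)
  if (nrow(bad))
    stop("patient ", bad$patient_id[1], " has only ", bad$n[1],
         " reader(s); inter-reader CoV needs at least 2")
  means |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(cov_percent = cov_percent(.data$value),
                     .groups = "drop")
}

#' Median (range) summary of CoV values
#'
#' Reproduces the reporting layout of reader studies: median and range of
#' the CoV, per grouping variable and for the overall pooled group.
#'
#' @param covs A tibble with a `cov_percent` column, e.g. from
#'   [intra_reader_cov()].
#' @param by Optional grouping column name (e.g. `"reader_id"`); the
#'   overall row is always appended.
#' @return A tibble with columns `group`, `n`, `median`, `min`, `max`.
#' @export
summarise_cov <- function(covs, by = NULL) {
  one <- function(d, label) {
    tibble::tibble(group = label, n = nrow(d),
                   median = median(d$cov_percent),
                   min = min(d$cov_percent), max = max(d$cov_percent))
  }
  out <- list()
  if (!is.null(by)) {
    out <- covs |>
      dplyr::group_split(.data[[by]]) |>
      purrr::map(~ one(.x, as.character(.x[[by]][1])))
  }
  dplyr::bind_rows(c(out, list(one(covs, "overall"))))
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater/measurement
#' intraclass correlation, from the two-way ANOVA mean squares of a
#' complete targets-by-raters matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' with MSR the between-target, MSC the between-rater and MSE the residual
#' mean square. The 95% confidence interval uses the McGraw-Wong F-based
#' construction with Satterthwaite degrees of freedom. Reliability is
#' banded poor / moderate / good / excellent at 0.5 / 0.75 / 0.9.
#'
#' @param m Numeric matrix (or data frame) with one row per target and one
#'   column per rater; no missing cells.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `n_targets`, `n_raters`, `interpretation`, and the mean squares.
#' @export
icc_2_1 <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("ICC requires a complete matrix (missing cells found)")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("ICC needs at least 2 targets and 2 raters, got ", n, " x ", k)
  grand <- mean(m)
  sst <- sum((m - grand)^2)
  if (sst == 0) stop("ICC undefined for constant data")
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- (sst - k * sum((row_m - grand)^2) - n * sum((col_m - grand)^2)) /
    ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # McGraw & Wong F interval for the single-measurement agreement ICC
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_u <- qf(1 - alpha / 2, n - 1, v)
  f_l <- qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_u * mse) /
    (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_l * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_l * msr)

  interpretation <-
    if (icc < 0.5) "poor"
    else if (icc < 0.75) "moderate"
    else if (icc <= 0.9) "good"
    else "excellent"

  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 n_targets = n, n_raters = k,
                 interpretation = interpretation,
                 msr = msr, msc = msc, mse = mse,
                 conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f, %g%% CI [%.4f, %.4f] (%s reliability; %d targets x %d raters)\n",
              x$icc, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$interpretation, x$n_targets, x$n_raters))
  invisible(x)
}

#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(estimate = x$icc, conf.low = x$ci_low,
                 conf.high = x$ci_high, interpretation = x$interpretation)
}

#' @method glance icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_targets = x$n_targets, n_raters = x$n_raters,
                 interpretation = x$interpretation)
}

#' Inter-reader ICC from a reader table
#'
#' Builds the patients-by-readers matrix of repeat means for one parameter
#' and method and applies [icc_2_1()].
#'
#' @inheritParams intra_reader_cov
#' @return An `icc_result`.
#' @export
icc_from_table <- function(table, parameter, method) {
  check_param(parameter)
  tab <- method_subset(table, method)
  wide <- tab |>
    dplyr::group_by(.data$patient_id, .data$reader_id) |>
    dplyr::summarise(value = mean(.data[[parameter]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "reader_id", values_from = "value")
  icc_2_1(as.matrix(wide[, -1]))
}

#' Paired MI vs gCS comparisons of reader variability
#'
#' Per reader, a two-tailed matched-pairs Wilcoxon signed-rank test between
#' the MI and gCS intra-reader CoVs (paired over patients); for the overall
#' group, a two-tailed Mann-Whitney U test on the pooled CoVs; and for
#' inter-reader variability, a matched-pairs Wilcoxon test over patients.
#' Tests come from [stats::wilcox.test()].
#'
#' @param table A [reader_table()] containing both methods.
#' @param parameter `"ctrl_suv_mean"` or `"btv_cm3"`.
#' @return A tibble with columns `level`, `group`, `test`, `p_value`.
#' @export
compare_methods <- function(table, parameter) {
  check_param(parameter)
  # all-zero paired differences (the MI-vs-MI control case) leave the
  # signed-rank statistic undefined; report NA rather than fail
  safe_p <- function(x, y, paired) tryCatch(
    suppressWarnings(wilcox.test(x, y, paired = paired)$p.value),
    error = function(e) NA_real_)
  mi <- intra_reader_cov(table, parameter, "MI")
  cs <- intra_reader_cov(table, parameter, "gCS")
  paired <- dplyr::inner_join(mi, cs, by = c("patient_id", "reader_id"),
                              suffix = c("_mi", "_gcs"))
  per_reader <- paired |>
    dplyr::group_by(.data$reader_id) |>
    dplyr::group_split() |>
    purrr::map(function(d) tibble::tibble(
      level = "intra-reader", group = as.character(d$reader_id[1]),
      test = "wilcoxon-signed-rank",
      p_value = safe_p(d$cov_percent_mi, d$cov_percent_gcs, TRUE))) |>
    dplyr::bind_rows()
  overall <- tibble::tibble(
    level = "intra-reader", group = "overall", test = "mann-whitney-u",
    p_value = safe_p(mi$cov_percent, cs$cov_percent, FALSE))
  mi_inter <- inter_reader_cov(table, parameter, "MI")
  cs_inter <- inter_reader_cov(table, parameter, "gCS")
  inter <- dplyr::inner_join(mi_inter, cs_inter, by = "patient_id",
                             suffix = c("_mi", "_gcs"))
  inter_row <- tibble::tibble(
    level = "inter-reader", group = "overall", test = "wilcoxon-signed-rank",
    p_value = safe_p(inter$cov_percent_mi, inter$cov_percent_gcs, TRUE))
  dplyr::bind_rows(per_reader, overall, inter_row)
}

#' Full reliability report for a reader study
#'
#' For every parameter and method present in the table: per-cell
#' intra-reader CoVs with the median (range) summary per reader and
#' overall, per-patient inter-reader CoVs with the overall summary, and
#' the inter-reader ICC(2,1). When both methods are present the paired
#' MI vs gCS tests are appended.
#'
#' @param table A [reader_table()].
#' @return An object of class `reliability_report`: a list of tibbles
#'   (`intra`, `intra_summary`, `inter`, `inter_summary`, `icc`,
#'   `comparisons`).
#' @export
reliability_report <- function(table) {
  table <- reader_table(table)
  methods <- unique(table$method)
  params <- c("ctrl_suv_mean", "btv_cm3")
  grid <- tidyr::expand_grid(parameter = params, method = methods)
  parts <- purrr::pmap(grid, function(parameter, method) {
    intra <- intra_reader_cov(table, parameter, method)
    inter <- inter_reader_cov(table, parameter, method)
    list(
      intra = dplyr::mutate(intra, parameter = parameter, method = method),
      intra_summary = dplyr::mutate(summarise_cov(intra, by = "reader_id"),
                                    parameter = parameter, method = method),
      inter = dplyr::mutate(inter, parameter = parameter, method = method),
      inter_summary = dplyr::mutate(summarise_cov(inter),
                                    parameter = parameter, method = method),
      # ICC needs >= 2 patients; single-phantom studies get an NA row
      icc = dplyr::mutate(
        tryCatch(glance(icc_from_table(table, parameter, method)),
                 error = function(e)
                   tibble::tibble(icc = NA_real_, ci_low = NA_real_,
                                  ci_high = NA_real_,
                                  n_targets = NA_integer_,
                                  n_raters = NA_integer_,
                                  interpretation = NA_character_)),
        parameter = parameter, method = method))
  })
  pull <- function(name) dplyr::bind_rows(purrr::map(parts, name))
  comparisons <- NULL
  if (all(c("MI", "gCS") %in% methods))
    comparisons <- dplyr::bind_rows(purrr::map(params, function(p)
      dplyr::mutate(compare_methods(table, p), parameter = p)))
  structure(list(intra = pull("intra"),
                 intra_summary = pull("intra_summary"),
                 inter = pull("inter"),
                 inter_summary = pull("inter_summary"),
                 icc = pull("icc"),
                 comparisons = comparisons),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  fmt_row <- function(d)
    sprintf("  %-12s %s%% (%s-%s%%)", d$group,
            signif(d$median, 3), signif(d$min, 3), signif(d$max, 3))
  for (p in unique(x$intra_summary$parameter)) {
    cat("==", p, "==\n")
    for (m in unique(x$intra_summary$method)) {
      cat(" intra-reader CoV,", m, "[median (range)]\n")
      d <- dplyr::filter(x$intra_summary,
                         .data$parameter == p, .data$method == m)
      cat(paste(vapply(seq_len(nrow(d)),
                       function(i) fmt_row(d[i, ]), ""), collapse = "\n"),
          "\n")
      di <- dplyr::filter(x$inter_summary,
                          .data$parameter == p, .data$method == m)
      cat(" inter-reader CoV,", m, ":",
          sprintf("%s%% (%s-%s%%)\n", signif(di$median, 3),
                  signif(di$min, 3), signif(di$max, 3)))
    }
  }
  if (!is.null(x$comparisons)) {
    cat("== MI vs gCS comparisons ==\n")
    print(x$comparisons, n = Inf)
  }
  invisible(x)
}

#' CoV distribution plot for a reliability report
#'
#' Boxplots of the per-cell intra-reader CoVs by method, one panel per
#' parameter — the at-a-glance MI vs gCS variability contrast.
#'
#' @param object A `reliability_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reliability_report
#' @export
autoplot.reliability_report <- function(object, ...) {
  ggplot2::ggplot(object$intra,
                  ggplot2::aes(x = .data$method, y = .data$cov_percent,
                               fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~ .data$parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "intra-reader CoV (%)",
                  title = "Reader variability by method") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
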