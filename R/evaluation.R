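#' Per-subject estimation errors
#'
#' Joins estimates with the subjects' true ages and computes the signed
#' error delta = estimated − real age (positive = overestimation), its
#' absolute value, and the integer age category (age rounded down to
#' the lowest whole year, as accuracy is conventionally reported).
#'
#' @param estimates tibble from [estimate_cohort()] (rows with
#'   `age_est = NA` are dropped with a warning, since a failed estimate
#'   carries no error).
#' @param records the stage records the estimates came from.
#' @return tibble `subject_id, method, sex, age_true, age_est, delta,
#'   abs_delta, age_category`.
#' @export
compute_errors <- function(estimates, records) {
  subjects <- subject_table(records)
  missing <- setdiff(estimates$subject_id, subjects$subject_id)
  if (length(missing) > 0) {
    dentage_abort(sprintf("estimate(s) without a matching record: %s",
                          paste(unique(missing), collapse = ", ")),
                  "dentage_error_join")
  }
  failed <- is.na(estimates$age_est)
  if (any(failed)) {
    warning(sprintf("dropping %d failed estimate(s)", sum(failed)),
            call. = FALSE)
    estimates <- estimates[!failed, ]
  }
  out <- dplyr::inner_join(
    estimates[, c("subject_id", "method", "age_est")],
    subjects, by = "subject_id"
  )
  tibble::tibble(
    subject_id = out$subject_id,
    method = out$method,
    sex = out$sex,
    age_true = out$age_true,
    age_est = out$age_est,
    delta = out$age_est - out$age_true,
    abs_delta = abs(out$age_est - out$age_true),
    age_category = as.integer(floor(out$age_true))
  )
}

#' Aggregate errors by age category
#'
#' For each method and age category: subject count, mean signed error
#' (bias), mean absolute error, and for each margin m the proportion of
#' subjects estimated correctly within m years.  An overall row
#' (`age_category = NA`) is computed over all subjects; because every
#' subject falls in exactly one category it equals the count-weighted
#' mean of the per-category values.
#'
#' @param errors tibble from [compute_errors()].
#' @param margins numeric vector of margins in years (default 1 and 2).
#' @param inclusive if `TRUE` (default) "correct within m years" means
#'   `abs_delta <= m`; if `FALSE`, strictly less.
#' @return tibble `method, age_category, n, mean_error, mean_abs_error`,
#'   plus one `rate_within_<m>` proportion column per margin; overall
#'   rows carry `age_category = NA`.
#' @export
aggregate_by_category <- function(errors, margins = c(1, 2),
                                  inclusive = TRUE) {
  if (nrow(errors) == 0) {
    dentage_abort("no errors to aggregate", "dentage_error_join")
  }
  if (any(margins <= 0)) {
    dentage_abort("margins must be positive", "dentage_error_config")
  }
  summarise_group <- function(df) {
    row <- tibble::tibble(
      n = nrow(df),
      mean_error = mean(df$delta),
      mean_abs_error = mean(df$abs_delta)
    )
    for (m in margins) {
      hit <- if (inclusive) df$abs_delta <= m else df$abs_delta < m
      row[[rate_col(m)]] <- mean(hit)
    }
    row
  }
  pieces <- list()
  for (meth in unique(errors$method)) {
    e <- errors[errors$method == meth, ]
    for (k in sort(unique(e$age_category))) {
      pieces[[length(pieces) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(method = meth, age_category = k),
        summarise_group(e[e$age_category == k, ])
      )
    }
    pieces[[length(pieces) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(method = meth, age_category = NA_integer_),
      summarise_group(e)
    )
  }
  dplyr::bind_rows(pieces)
}

rate_col <- function(margin) {
  sprintf("rate_within_%s", format(margin, trim = TRUE))
}

#' Count-weighted overall value from per-category values
#'
#' The "Total" row of a per-age accuracy table is the count-weighted
#' mean of the per-age values: sum(n * value) / sum(n).
#'
#' @param n non-negative counts per category.
#' @param values per-category values (means, rates, ...).
#' @return the weighted overall value.
#' @examples
#' weighted_totals(c(10, 10), c(1, 3))  # 2
#' @export
weighted_totals <- function(n, values) {
  if (length(n) != length(values) || any(n < 0)) {
    dentage_abort("counts and values must match, with n >= 0",
                  "dentage_error_config")
  }
  if (sum(n) == 0) {
    dentage_abort("total count is zero; overall value undefined",
                  "dentage_error_undefined_total")
  }
  sum(n * values) / sum(n)
}

#' Paired Student's t-test with an applicability note
#'
#' Classical paired t-test on the differences `a - b` (n − 1 degrees of
#' freedom, two-sided).  Applicability is checked before testing:
#' zero-variance differences are rejected as degenerate, and normality
#' of the differences is assessed with a Shapiro–Wilk test at alpha =
#' 0.05 for small samples (waived for n >= 30, where the central limit
#' theorem covers the t-test).  The outcome of that check is recorded
#' in the result's `note`, never used to alter the test.
#'
#' @param a,b paired numeric vectors of equal length (n >= 2).
#' @param label name for the comparison.
#' @return tibble `test, label, statistic, p_value, n, note`.
#' @export
paired_t_test <- function(a, b, label = "paired comparison") {
  if (length(a) != length(b) || length(a) < 2) {
    dentage_abort("paired test needs two equal-length vectors, n >= 2",
                  "dentage_error_config")
  }
  d <- a - b
  # sd at rounding-noise level means the differences are constant
  if (stats::sd(d) <= 1e-9 * max(abs(mean(d)), 1)) {
    dentage_abort("differences have zero variance; paired t-test degenerate",
                  "dentage_error_degenerate_test")
  }
  n <- length(d)
  note <- if (n >= 30) {
    sprintf("n = %d >= 30: normality check waived (central limit theorem)", n)
  } else {
    sw <- stats::shapiro.test(d)
    sprintf("Shapiro-Wilk on differences: W = %.3f, p = %.3g (%s at alpha 0.05)",
            sw$statistic, sw$p.value,
            if (sw$p.value < 0.05) "normality rejected" else
              "normality not rejected")
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  tibble::tibble(
    test = "paired t-test",
    label = label,
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    n = n,
    note = note
  )
}

#' Compare estimated with real ages
#'
#' Paired t-test of one method's estimated ages against the subjects'
#' chronological ages; a positive statistic means systematic
#' overestimation.
#'
#' @param errors tibble from [compute_errors()], one method.
#' @return tibble as from [paired_t_test()].
#' @export
estimated_vs_real <- function(errors) {
  meth <- unique(errors$method)
  if (length(meth) != 1) {
    dentage_abort("estimated_vs_real() takes one method's errors",
                  "dentage_error_config")
  }
  paired_t_test(errors$age_est, errors$age_true,
                label = sprintf("%s estimated vs real age", meth))
}

#' Compare two methods' absolute errors
#'
#' Pairs the two methods' absolute errors by subject and applies the
#' paired t-test; a positive statistic means method A is less accurate
#' (larger absolute errors) than method B.
#'
#' @param errors_a,errors_b error tibbles for the two methods, same
#'   subjects.
#' @return tibble as from [paired_t_test()].
#' @export
compare_methods <- function(errors_a, errors_b) {
  joined <- dplyr::inner_join(
    errors_a[, c("subject_id", "method", "abs_delta")],
    errors_b[, c("subject_id", "method", "abs_delta")],
    by = "subject_id", suffix = c("_a", "_b")
  )
  if (nrow(joined) != nrow(errors_a) || nrow(joined) != nrow(errors_b)) {
    dentage_abort("the two error sets do not cover the same subjects",
                  "dentage_error_join")
  }
  paired_t_test(joined$abs_delta_a, joined$abs_delta_b,
                label = sprintf("|error| %s vs %s", joined$method_a[1],
                                joined$method_b[1]))
}

#' Study-style accuracy tables
#'
#' Renders aggregated errors as two display tables: per-age mean signed
#' and absolute errors per method (with counts and percentages of the
#' sample), and per-age correct-estimation rates per method and margin
#' in percent.  Values are rounded to 2 decimals at this display step
#' only; machine-readable highlight flags mark rates of exactly 100%
#' and rates above 50%.
#'
#' @param errors tibble from [compute_errors()] (any number of methods).
#' @param margins margins in years, as for [aggregate_by_category()].
#' @param inclusive margin inclusivity, as for [aggregate_by_category()].
#' @return list of tibbles `table1` (errors), `table2` (rates in
#'   percent) and `table2_flags` (long, with `highlight_100` /
#'   `highlight_gt50`).
#' @export
report_tables <- function(errors, margins = c(1, 2), inclusive = TRUE) {
  agg <- aggregate_by_category(errors, margins, inclusive)
  agg$row_label <- ifelse(is.na(agg$age_category), "Total",
                          as.character(agg$age_category))
  methods <- unique(agg$method)

  total_n <- sum(agg$n[is.na(agg$age_category) & agg$method == methods[1]])
  base <- agg[agg$method == methods[1], c("row_label", "n")]
  base$pct_of_total <- round(100 * base$n / total_n, 2)
  table1 <- base
  for (meth in methods) {
    sub <- agg[agg$method == meth, ]
    table1[[paste0(meth, "_mean_error")]] <- round(sub$mean_error, 2)
    table1[[paste0(meth, "_mean_abs_error")]] <- round(sub$mean_abs_error, 2)
  }

  table2 <- agg[agg$method == methods[1], c("row_label", "n")]
  flags <- list()
  for (meth in methods) {
    sub <- agg[agg$method == meth, ]
    for (m in margins) {
      pct <- 100 * sub[[rate_col(m)]]
      table2[[sprintf("%s_%sy_pct", meth, format(m, trim = TRUE))]] <-
        round(pct, 2)
      flags[[length(flags) + 1L]] <- tibble::tibble(
        row_label = sub$row_label, method = meth, margin = m,
        rate_pct = round(pct, 2),
        highlight_100 = abs(pct - 100) < 1e-9,
        highlight_gt50 = pct > 50
      )
    }
  }
  list(table1 = tibble::as_tibble(table1),
       table2 = tibble::as_tibble(table2),
       table2_flags = dplyr::bind_rows(flags))
}

#' Plot mean signed error by age category
#'
#' @param errors tibble from [compute_errors()].
#' @return a ggplot object.
#' @export
plot_mean_error <- function(errors) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    dentage_abort("ggplot2 is required for plotting", "dentage_error_config")
  }
  agg <- aggregate_by_category(errors, margins = 1)
  agg <- agg[!is.na(agg$age_category), ]
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$age_category,
                                    y = .data$mean_error,
                                    colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "age category (years, rounded down)",
                  y = "mean signed error (years)", colour = NULL)
}
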