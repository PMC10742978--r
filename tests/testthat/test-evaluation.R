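errors_from <- function(age_true, age_est, method = "NOLLA",
                        ids = sprintf("S%03d", seq_along(age_true))) {
  est <- tibble::tibble(subject_id = ids, method = method,
                        age_est = age_est, score = NA_real_, clamped = FALSE,
                        olze_triggered = NA, n_substitutions = 0L,
                        substitutions = "", note = "")
  rec <- tibble::tibble(subject_id = ids, sex = "male", age_true = age_true,
                        fdi = 31L, scheme = "NOLLA", stage = "5",
                        present = TRUE)
  suppressWarnings(compute_errors(est, rec))
}

test_that("signed error, absolute error and age category follow the conventions", {
  e <- errors_from(10.0, 10.0)
  expect_equal(e$delta, 0)
  expect_equal(e$abs_delta, 0)
  expect_equal(e$age_category, 10L)

  e <- errors_from(17 + 11 / 12, 16.5)
  expect_equal(e$delta, -1.41667, tolerance = 1e-4)
  expect_equal(e$age_category, 17L)   # floor of 17.917

  e <- errors_from(4.0, 6.02)
  expect_equal(e$delta, 2.02)
  expect_equal(e$age_category, 4L)

  # overestimation by construction gives mean error +1
  e <- errors_from(c(5, 9.25, 14.5), c(5, 9.25, 14.5) + 1)
  expect_equal(mean(e$delta), 1)
})

test_that("an estimate without a matching record is a join error", {
  est <- tibble::tibble(subject_id = "ghost", method = "NOLLA", age_est = 5)
  rec <- tibble::tibble(subject_id = "S1", sex = "male", age_true = 5,
                        fdi = 31L, scheme = "NOLLA", stage = "5",
                        present = TRUE)
  expect_error(compute_errors(est, rec), regexp = "ghost",
               class = "dentage_error_join")
})

test_that("category aggregation computes counts, means and margin rates", {
  e <- errors_from(10.2, 10.7)
  agg <- aggregate_by_category(e)
  row <- agg[!is.na(agg$age_category), ]
  expect_equal(row$n, 1)
  expect_equal(row$mean_error, 0.5)
  expect_equal(row$mean_abs_error, 0.5)
  expect_equal(row$rate_within_1, 1)

  # deltas 0.5, -1.0, 1.5 (binary-exact, so the margin boundary is exact)
  e <- errors_from(c(8, 8.5, 8.25), c(8.5, 7.5, 9.75))
  agg <- aggregate_by_category(e, margins = 1)
  expect_equal(agg$rate_within_1[agg$age_category %in% 8], 2 / 3)
  # the margin rule is inclusive by default, exclusive on request
  agg <- aggregate_by_category(errors_from(7, 8), margins = 1)
  expect_equal(agg$rate_within_1, c(1, 1))
  agg <- aggregate_by_category(errors_from(7, 8), margins = 1,
                               inclusive = FALSE)
  expect_equal(agg$rate_within_1, c(0, 0))
})

test_that("the overall row equals the count-weighted mean of category rows", {
  set.seed(7)
  age <- runif(60, 4, 21)
  e <- errors_from(age, age + rnorm(60))
  agg <- aggregate_by_category(e, margins = c(1, 2))
  per <- agg[!is.na(agg$age_category), ]
  tot <- agg[is.na(agg$age_category), ]
  for (col in c("mean_error", "mean_abs_error", "rate_within_1",
                "rate_within_2")) {
    expect_equal(weighted_totals(per$n, per[[col]]), tot[[col]])
  }
  # margin rates are monotone in the margin and reach 1 eventually
  wide <- aggregate_by_category(e, margins = c(0.5, 1, 2, 50))
  expect_true(all(wide$rate_within_0.5 <= wide$rate_within_1))
  expect_true(all(wide$rate_within_1 <= wide$rate_within_2))
  expect_true(all(wide$rate_within_50 == 1))
})

test_that("weighted totals are the count-weighted mean", {
  expect_equal(weighted_totals(c(10, 10), c(1, 3)), 2)
  expect_equal(weighted_totals(c(1, 3), c(0, 4)), 3)
  expect_error(weighted_totals(c(0, 0), c(1, 2)),
               class = "dentage_error_undefined_total")
  expect_error(weighted_totals(c(1, -1), c(1, 2)),
               class = "dentage_error_config")
})

test_that("the paired t statistic matches the closed form and brute force", {
  r <- paired_t_test(c(2, 4, 6, 8), c(1, 2, 3, 4))  # d = 1,2,3,4
  expect_equal(r$statistic, 2.5 / (sd(1:4) / 2), tolerance = 1e-10)
  expect_equal(r$statistic, 3.8730, tolerance = 1e-4)
  expect_equal(r$n, 4)

  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    d <- a - b
    brute <- mean(d) / sqrt((sum(d^2) - sum(d)^2 / n) / (n - 1) / n)
    expect_equal(paired_t_test(a, b)$statistic, brute, tolerance = 1e-10)
  }
})

test_that("degenerate paired input is rejected, applicability is noted", {
  x <- c(1, 2, 3)
  expect_error(paired_t_test(x, x), class = "dentage_error_degenerate_test")
  expect_error(paired_t_test(x, x + 2), class = "dentage_error_degenerate_test")
  expect_match(paired_t_test(rnorm(10), rnorm(10))$note, "Shapiro")
  expect_match(paired_t_test(rnorm(40), rnorm(40))$note, "central limit")
})

test_that("the paired test detects a real bias almost surely at n = 324", {
  set.seed(23)
  hits <- vapply(1:200, function(i) {
    age <- runif(324, 4, 21)
    est <- age + 0.5 + rnorm(324, 0, 1)  # 0.5-year overestimation
    paired_t_test(est, age)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("method comparison pairs absolute errors by subject", {
  set.seed(3)
  age <- runif(50, 5, 20)
  ea <- errors_from(age, age + rnorm(50, 0, 0.8), method = "NOLLA")
  eb <- ea
  eb$method <- "LONDON_ATLAS"
  # B systematically ~0.5 y less accurate than A (jitter keeps the
  # paired differences non-degenerate)
  eb$abs_delta <- eb$abs_delta + 0.5 + abs(rnorm(50, 0, 0.05))
  r <- compare_methods(eb, ea)
  expect_gt(r$statistic, 0)
  r <- compare_methods(ea, eb)
  expect_lt(r$statistic, 0)

  expect_error(compare_methods(ea, ea),
               class = "dentage_error_degenerate_test")
  expect_error(compare_methods(ea, eb[1:10, ]), class = "dentage_error_join")
})

test_that("report tables round for display and flag headline rates", {
  age <- c(5.5, 5.8, 9.1, 9.4)
  perfect <- errors_from(age, age + c(0.2, -0.3, 0.1, 0))
  rep <- report_tables(perfect)
  expect_true(all(rep$table2_flags$highlight_100))
  expect_true(all(rep$table2_flags$rate_pct == 100))

  mixed <- errors_from(age, age + c(0.2, 2.5, 0.4, 0.1))
  rep <- report_tables(mixed, margins = 1)
  f <- rep$table2_flags
  expect_false(any(f$highlight_100[f$row_label == "5"]))
  # category 5 sits exactly at 50%: above-half highlighting is strict
  expect_equal(f$highlight_gt50[match(c("5", "9", "Total"), f$row_label)],
               c(FALSE, TRUE, TRUE))
  expect_equal(f$rate_pct[f$row_label == "Total"], 75)

  # no margins requested: tables carry no rate columns
  rep <- report_tables(mixed, margins = numeric(0))
  expect_equal(setdiff(names(rep$table2), c("row_label", "n")), character(0))

  # stable under subject reordering
  shuffled <- mixed[c(3, 1, 4, 2), ]
  expect_equal(report_tables(shuffled, margins = 1), rep2 <- report_tables(mixed, margins = 1))
})
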