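test_that("maturity score is the sum of the seven self-weighted scores", {
  tb <- tiny_tables()
  zero <- make_subject(full_row("DEMIRJIAN", rep("0", 7)))
  expect_equal(demirjian_maturity_score(zero, tb)$score, 0)

  # stage D at every position reproduces the hand sum 39.6
  d <- make_subject(full_row("DEMIRJIAN", rep("D", 7)))
  ms <- demirjian_maturity_score(d, tb)
  expect_equal(ms$score, 39.6)
  expect_equal(ms$stages_used$score,
               c(1.7, 3.1, 5.4, 4.0, 7.3, 10.1, 8.0))
})

test_that("a missing left tooth is substituted by its right counterpart", {
  tb <- tiny_tables()
  stages <- full_row("DEMIRJIAN", rep("D", 6), positions = 1:6)
  stages["DEMIRJIAN:47"] <- "D"
  subj <- make_subject(stages, absent = "DEMIRJIAN:37")
  ms <- demirjian_maturity_score(subj, tb)
  expect_equal(ms$score, 39.6)
  expect_equal(ms$substitutions, "37<-47")

  none <- make_subject(full_row("DEMIRJIAN", rep("D", 6), positions = 1:6))
  expect_error(demirjian_maturity_score(none, tb),
               class = "dentage_error_incomplete")
})

test_that("score-to-age conversion uses knots, midpoints and interpolation", {
  tb <- tiny_tables()$demirjian_age$male
  expect_equal(demirjian_age(90, tb)$age, 14)     # knot identity
  expect_equal(demirjian_age(92, tb)$age, 14.5)   # exact midpoint: mean
  expect_equal(demirjian_age(93, tb)$age, 14.75)  # linear interpolation
  expect_true(demirjian_age(100, tb)$clamped == FALSE)
  expect_error(demirjian_age(101, tb), class = "dentage_error_stage")
  expect_error(demirjian_age(-2, tb), class = "dentage_error_stage")
})

test_that("the midpoint rule and linear interpolation agree at every midpoint", {
  tb <- tiny_tables()$demirjian_age$male
  for (i in seq_len(nrow(tb) - 1)) {
    mid <- (tb$score[i] + tb$score[i + 1]) / 2
    expect_equal(demirjian_age(mid, tb)$age,
                 (tb$age[i] + tb$age[i + 1]) / 2)
  }
})

test_that("Olze reads tooth 38, falling back to 48, mapping stage to age", {
  tb <- tiny_tables()
  subj <- make_subject(c("DEMIRJIAN:38" = "F"))
  o <- olze_age(subj, tb)
  expect_equal(o$age, 17.4)
  expect_equal(o$fdi_used, 38L)
  expect_false(o$substituted)

  subj <- make_subject(c("DEMIRJIAN:48" = "F"), absent = "DEMIRJIAN:38")
  o <- olze_age(subj, tb)
  expect_equal(o$age, 17.4)
  expect_equal(o$fdi_used, 48L)
  expect_true(o$substituted)

  expect_null(olze_age(make_subject(c("DEMIRJIAN:31" = "D")), tb))
  expect_error(olze_age(make_subject(c("DEMIRJIAN:38" = "A")), tb),
               class = "dentage_error_unmapped_stage")
})

test_that("the Olze supplement replaces the base age only above the threshold", {
  tb <- tiny_tables()
  # stage D everywhere: S = 39.6 -> 9.7 years, far below the trigger
  low <- make_subject(c(full_row("DEMIRJIAN", rep("D", 7)),
                        "DEMIRJIAN:38" = "F"))
  est <- estimate_demirjian_olze(low, tb)
  expect_equal(est$age_est, 9.7)
  expect_false(est$intermediate$olze_attempted)
  expect_false(est$intermediate$olze_triggered)

  # stage H everywhere: S = 100 -> 16.9 years > 16, third molar at G
  high <- make_subject(c(full_row("DEMIRJIAN", rep("H", 7)),
                         "DEMIRJIAN:38" = "G"))
  est <- estimate_demirjian_olze(high, tb)
  expect_true(est$intermediate$olze_triggered)
  expect_equal(est$age_est, 19.1)
  expect_equal(est$intermediate$base_age, 16.9)
  expect_equal(est$intermediate$olze_tooth, 38L)

  # triggered but no third molar assessable: base age stands, attempt logged
  bare <- make_subject(full_row("DEMIRJIAN", rep("H", 7)),
                       absent = c("DEMIRJIAN:38", "DEMIRJIAN:48"))
  est <- estimate_demirjian_olze(bare, tb)
  expect_equal(est$age_est, 16.9)
  expect_true(est$intermediate$olze_attempted)
  expect_false(est$intermediate$olze_triggered)

  # the threshold is strict: a base age of exactly 16 is not supplemented
  est <- estimate_demirjian_olze(high, tb, olze_threshold = 16.9)
  expect_false(est$intermediate$olze_attempted)
  expect_equal(est$age_est, 16.9)
})
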