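# handcrafted miniature table set with known lookup values; every
# engine test that needs exact expected ages uses these tables
tiny_tables <- function() {
  nolla_knots <- tibble::tibble(
    sum_value = c(7, 35, 60.9, 70),
    age = c(3, 8, 11.3, 17)
  )
  nolla3m_knots <- tibble::tibble(
    sum_value = c(10, 80),
    age = c(3, 18)
  )
  nolla <- list()
  for (s in c("male", "female")) {
    nolla[[length(nolla) + 1L]] <- list(
      sex = s, jaw_scope = "mandible", includes_third_molars = FALSE,
      knots = nolla_knots)
    nolla[[length(nolla) + 1L]] <- list(
      sex = s, jaw_scope = "mandible", includes_third_molars = TRUE,
      knots = nolla3m_knots)
  }

  # per-position weights chosen so the stage-D row reproduces the
  # hand-sum example scores {1.7, 3.1, 5.4, 4.0, 7.3, 10.1, 8.0};
  # stage H gets a top-up so the maximal maturity score is exactly 100
  base <- c(1.7, 3.1, 5.4, 4.0, 7.3, 10.1, 8.0) / 4
  h_extra <- (100 - 8 * sum(base)) / 7
  scores <- do.call(rbind, lapply(1:7, function(p) {
    idx <- 0:8
    sc <- idx * base[p]
    sc[9] <- sc[9] + h_extra
    data.frame(position = p, stage = c("0", LETTERS[1:8]), score = sc)
  }))
  demirjian_scores <- list(male = tibble::as_tibble(scores),
                           female = tibble::as_tibble(scores))

  age_knots <- tibble::tibble(
    score = c(0, 39.6, 90, 94, 100),
    age = c(3, 9.7, 14, 15, 16.9)
  )
  demirjian_age <- list(male = age_knots, female = age_knots)

  olze_tbl <- tibble::tibble(
    stage = c("D", "E", "F", "G", "H"),
    age = c(15.5, 16.5, 17.4, 19.1, 20.5)
  )
  olze <- list(male = olze_tbl, female = olze_tbl)

  # monotone 4-tooth charts; observed (3,3,4,4) ties 9.5 and 10.5
  chart_teeth <- c(11L, 16L, 41L, 46L)
  atlas <- dplyr::bind_rows(lapply(seq_along(ages <- c(8.5, 9.5, 10.5, 11.5, 12)),
    function(i) tibble::tibble(chart_age = ages[i], fdi = chart_teeth,
                               stage = i + 1L)))

  new_table_set(nolla, demirjian_scores, demirjian_age, olze, atlas,
                provenance = "tiny synthetic test tables")
}

# one-subject record builder: stages is a named character vector
# "<scheme>:<fdi>" -> token; absent teeth can be forced with NA
make_subject <- function(stages, sid = "S1", sex = "male", age = 10,
                         absent = character(0)) {
  keys <- c(names(stages), absent)
  parts <- strsplit(keys, ":", fixed = TRUE)
  tibble::tibble(
    subject_id = sid,
    sex = sex,
    age_true = age,
    fdi = as.integer(vapply(parts, `[`, "", 2)),
    scheme = vapply(parts, `[`, "", 1),
    stage = c(unname(stages), rep(NA_character_, length(absent))),
    present = c(rep(TRUE, length(stages)), rep(FALSE, length(absent)))
  )
}

# all seven left mandibular teeth staged under one scheme
full_row <- function(scheme, tokens, positions = 1:7, quadrant = 3L) {
  stats::setNames(tokens, sprintf("%s:%d", scheme, quadrant * 10L + positions))
}

noise_free_model <- function(...) {
  maturation_model(individual_effect_sd = 0, observation_noise = 0,
                   missing_prob = 0, ...)
}

small_spec <- function(per_cat = 2L, categories = 4:20,
                       n_female = NULL) {
  counts <- stats::setNames(rep(per_cat, length(categories)),
                            as.character(categories))
  if (is.null(n_female)) n_female <- floor(sum(counts) / 2)
  cohort_spec(counts = counts, n_female = n_female)
}
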