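#' Demirjian maturity score
#'
#' Each of the seven left mandibular teeth (positions 1–7, FDI 31–37) is
#' assigned a letter stage A–H ("0" before calcification starts), which
#' a sex-specific table converts to a self-weighted score; the seven
#' scores sum to the total maturity score S on a 0–100 scale.  A left
#' tooth that cannot be assessed is substituted by its right
#' counterpart.
#'
#' @param subject_records one subject's stage-record rows.
#' @param tables a `dentage_tables` object.
#' @return list with `score` (S), `stages_used` (tibble of
#'   `position, fdi, stage, score, substituted`) and `substitutions`.
#' @export
demirjian_maturity_score <- function(subject_records, tables) {
  sex <- subject_records$sex[1]
  score_table <- tables$demirjian_scores[[sex]]
  if (is.null(score_table)) {
    dentage_abort(sprintf("no Demirjian score table for sex %s", sex),
                  "dentage_error_table")
  }
  used <- list()
  subs <- character(0)
  total <- 0
  for (p in 1:7) {
    left_fdi <- 30L + p
    hit <- contralateral_substitute(subject_records, left_fdi, "DEMIRJIAN")
    if (is.null(hit)) {
      dentage_abort(
        sprintf("incomplete dentition: no Demirjian stage for position %d (teeth %d/%d)",
                p, left_fdi, contralateral(left_fdi)),
        "dentage_error_incomplete"
      )
    }
    row <- score_table[score_table$position == p &
                         score_table$stage == hit$stage, ]
    if (nrow(row) != 1) {
      dentage_abort(
        sprintf("stage '%s' unscored for position %d in the %s table",
                hit$stage, p, sex),
        "dentage_error_table"
      )
    }
    total <- total + row$score[1]
    used[[p]] <- tibble::tibble(position = p, fdi = hit$fdi_used,
                                stage = hit$stage, score = row$score[1],
                                substituted = hit$substituted)
    if (hit$substituted) subs <- c(subs, sub_label(left_fdi, hit$fdi_used))
  }
  list(score = total, stages_used = dplyr::bind_rows(used),
       substitutions = subs)
}

#' Convert a maturity score to dental age
#'
#' A score hitting a tabulated knot returns that knot's age; a score
#' exactly midway between two knots returns the average of their ages; a
#' score strictly between knots is linearly interpolated (which contains
#' the midpoint rule as a special case); a score outside the table is
#' clamped to the boundary age and flagged — the standard tables only
#' reach 16 years, so older subjects saturate here.
#'
#' @param score total maturity score S in \[0, 100\].
#' @param age_table tibble `(score, age)` with strictly increasing
#'   scores.
#' @return list with `age` and `clamped`.
#' @export
demirjian_age <- function(score, age_table) {
  if (is.na(score) || score < -1e-9 || score > 100 + 1e-9) {
    dentage_abort("maturity score must lie in [0, 100]", "dentage_error_stage")
  }
  lookup_age(age_table, min(max(score, 0), 100))
}

#' Third-molar age by Olze's table
#'
#' Reads tooth 38's Demirjian stage (tooth 48 when 38 is missing) and
#' maps it directly to age through the sex-specific Olze table.
#'
#' @param subject_records one subject's stage-record rows.
#' @param tables a `dentage_tables` object.
#' @return `NULL` when neither third molar is assessable, otherwise a
#'   list with `age`, `fdi_used`, `stage` and `substituted`.
#' @export
olze_age <- function(subject_records, tables) {
  hit <- contralateral_substitute(subject_records, 38L, "DEMIRJIAN")
  if (is.null(hit)) return(NULL)
  sex <- subject_records$sex[1]
  tb <- tables$olze[[sex]]
  if (is.null(tb)) {
    dentage_abort(sprintf("no Olze table for sex %s", sex),
                  "dentage_error_table")
  }
  row <- tb[tb$stage == hit$stage, ]
  if (nrow(row) != 1) {
    dentage_abort(sprintf("third-molar stage '%s' not mapped in the %s Olze table",
                          hit$stage, sex),
                  "dentage_error_unmapped_stage")
  }
  list(age = row$age[1], fdi_used = hit$fdi_used, stage = hit$stage,
       substituted = hit$substituted)
}

#' Estimate age with Demirjian's method, supplemented by Olze's
#'
#' Computes the Demirjian maturity-score age first.  When that base age
#' strictly exceeds `olze_threshold` (16 years by default — the ceiling
#' of the standard maturity tables), the third-molar Olze age replaces
#' it, provided a third molar is assessable; both ages are kept in the
#' result's `intermediate`.
#'
#' @param subject_records one subject's stage-record rows.
#' @param tables a `dentage_tables` object.
#' @param olze_threshold base-age threshold (years) above which the
#'   third-molar supplement is applied.
#' @return a `dentage_estimate`; `intermediate$olze_triggered` records
#'   whether the supplement replaced the base age.
#' @export
estimate_demirjian_olze <- function(subject_records, tables,
                                    olze_threshold = 16) {
  sex <- subject_records$sex[1]
  ms <- demirjian_maturity_score(subject_records, tables)
  base <- demirjian_age(ms$score, tables$demirjian_age[[sex]])
  subs <- ms$substitutions
  olze <- NULL
  triggered <- FALSE
  attempted <- FALSE
  if (base$age > olze_threshold) {
    attempted <- TRUE
    olze <- olze_age(subject_records, tables)
    triggered <- !is.null(olze)
    if (triggered && olze$substituted) {
      subs <- c(subs, sub_label(38L, olze$fdi_used))
    }
  }
  new_estimate(
    method = "DEMIRJIAN_OLZE",
    age_est = if (triggered) olze$age else base$age,
    intermediate = list(
      maturity_score = ms$score,
      base_age = base$age,
      olze_attempted = attempted,
      olze_triggered = triggered,
      olze_age = if (triggered) olze$age else NA_real_,
      olze_tooth = if (triggered) olze$fdi_used else NA_integer_,
      stages_used = ms$stages_used
    ),
    substitutions = subs,
    clamped = if (triggered) FALSE else base$clamped
  )
}
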