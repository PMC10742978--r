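#' Dentition stage records
#'
#' A cohort of stage records is a tidy tibble with one row per
#' (subject, tooth, scheme):
#'
#' * `subject_id` — opaque string.
#' * `sex` — `"male"` or `"female"`.
#' * `age_true` — chronological age in decimal years at one-month
#'   resolution (years + months/12).
#' * `fdi` — two-digit FDI tooth code.
#' * `scheme` — `"NOLLA"`, `"DEMIRJIAN"` or `"ATLAS"`.
#' * `stage` — scheme-specific stage token (see [staging]); `NA` when the
#'   tooth is not observable.
#' * `present` — `FALSE` when the tooth cannot be assessed on the image.
#'
#' `validate_records()` checks this contract and returns its input
#' invisibly; ages outside the study-emulating range 4–21 years only
#' raise a warning, since the engines themselves have no such limit.
#'
#' @param records a tibble as described above.
#' @return the validated records, invisibly.
#' @export
validate_records <- function(records) {
  needed <- c("subject_id", "sex", "age_true", "fdi", "scheme", "stage", "present")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    dentage_abort(sprintf("records missing column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "dentage_error_parse")
  }
  if (!all(records$sex %in% c("male", "female"))) {
    dentage_abort("sex must be 'male' or 'female'", "dentage_error_parse")
  }
  stopifnot_fdi(records$fdi)
  if (!all(records$scheme %in% dentage_schemes)) {
    dentage_abort(sprintf("unknown scheme(s): %s",
                          paste(setdiff(records$scheme, dentage_schemes),
                                collapse = ", ")),
                  "dentage_error_parse")
  }
  staged <- records$present & !is.na(records$stage)
  ok <- is_valid_stage_token(records$scheme[staged], records$stage[staged])
  if (!all(ok)) {
    bad <- records[staged, ][!ok, ]
    dentage_abort(sprintf("invalid stage token(s): %s",
                          paste(sprintf("%s/%s='%s'", bad$scheme, bad$fdi,
                                        bad$stage), collapse = ", ")),
                  "dentage_error_parse")
  }
  if (any(!records$present & !is.na(records$stage))) {
    dentage_abort("a missing tooth (present = FALSE) must carry no stage",
                  "dentage_error_parse")
  }
  key <- paste(records$subject_id, records$fdi, records$scheme)
  if (anyDuplicated(key)) {
    dentage_abort(sprintf("duplicate (subject, tooth, scheme) assessment(s): %s",
                          paste(unique(key[duplicated(key)]), collapse = "; ")),
                  "dentage_error_duplicate")
  }
  per_subj <- unique(records[, c("subject_id", "age_true")])
  if (anyDuplicated(per_subj$subject_id)) {
    dentage_abort("inconsistent age_true within a subject", "dentage_error_parse")
  }
  out_of_range <- per_subj$age_true < 4 | per_subj$age_true > 21
  if (any(out_of_range)) {
    warning(sprintf("%d subject(s) outside the 4-21 year study range",
                    sum(out_of_range)), call. = FALSE)
  }
  invisible(records)
}

#' Subjects summarised one row each (id, sex, true age).
#' @param records stage records, see [validate_records()].
#' @return a tibble with columns `subject_id`, `sex`, `age_true`.
#' @export
subject_table <- function(records) {
  tibble::as_tibble(unique(records[, c("subject_id", "sex", "age_true")]))
}

#' Fetch a tooth's assessment, substituting the contralateral tooth
#'
#' Returns the stage assessment for `fdi` under `scheme` if the tooth is
#' present and staged; otherwise the contralateral tooth's assessment,
#' flagged as substituted (the study itself read tooth 48 when 38 was
#' missing, and left/right development is near-identical); otherwise
#' `NULL`.
#'
#' @param subject_records one subject's rows of a stage-record tibble.
#' @param fdi the preferred tooth.
#' @param scheme staging scheme tag.
#' @return `NULL`, or a list with `fdi_used`, `stage`, `substituted`.
#' @export
contralateral_substitute <- function(subject_records, fdi, scheme) {
  pick <- function(code) {
    row <- subject_records[subject_records$fdi == code &
                             subject_records$scheme == scheme, ]
    if (nrow(row) == 1 && row$present[1] && !is.na(row$stage[1])) {
      row$stage[1]
    } else {
      NULL
    }
  }
  fdi <- stopifnot_fdi(fdi)
  own <- pick(fdi)
  if (!is.null(own)) {
    return(list(fdi_used = fdi, stage = own, substituted = FALSE))
  }
  other <- contralateral(fdi)
  sub <- pick(other)
  if (!is.null(sub)) {
    return(list(fdi_used = other, stage = sub, substituted = TRUE))
  }
  NULL
}
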