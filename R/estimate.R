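#' Estimate ages for a whole cohort
#'
#' Runs the selected engines over every subject and flattens the
#' results into a tibble (one row per subject and method) suitable for
#' [compute_errors()] and for writing to delimited text.  A subject an
#' engine cannot handle (incomplete dentition, unmapped stage, ...)
#' yields a row with `age_est = NA` and the condition message in
#' `note`, so one bad dentition does not abort a cohort run.
#'
#' @param records a validated stage-record tibble.
#' @param tables a `dentage_tables` object.
#' @param methods subset of `c("nolla", "demirjian_olze", "atlas")`.
#' @param jaw_scope,include_third_molars passed to [estimate_nolla()].
#' @param olze_threshold passed to [estimate_demirjian_olze()].
#' @return tibble with columns `subject_id, method, age_est, score,
#'   clamped, olze_triggered, n_substitutions, substitutions, note`.
#'   `score` is the Nolla sum of values, the Demirjian maturity score,
#'   or the atlas mismatch, by method.
#' @export
estimate_cohort <- function(records, tables,
                            methods = c("nolla", "demirjian_olze", "atlas"),
                            jaw_scope = "mandible",
                            include_third_molars = NULL,
                            olze_threshold = 16) {
  validate_records(records)
  methods <- match.arg(methods, c("nolla", "demirjian_olze", "atlas"),
                       several.ok = TRUE)
  subjects <- subject_table(records)
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    subj <- records[records$subject_id == sid, ]
    for (m in methods) {
      est <- tryCatch(
        switch(m,
          nolla = estimate_nolla(subj, tables, jaw_scope,
                                 include_third_molars),
          demirjian_olze = estimate_demirjian_olze(subj, tables,
                                                   olze_threshold),
          atlas = estimate_london_atlas(subj, tables)
        ),
        dentage_error = function(e) e
      )
      rows[[length(rows) + 1L]] <- if (inherits(est, "dentage_estimate")) {
        tibble::tibble(
          subject_id = sid,
          method = est$method,
          age_est = est$age_est,
          score = switch(est$method,
                         NOLLA = est$intermediate$sum_of_values,
                         DEMIRJIAN_OLZE = est$intermediate$maturity_score,
                         LONDON_ATLAS = est$intermediate$mismatch),
          clamped = est$clamped,
          olze_triggered = if (est$method == "DEMIRJIAN_OLZE")
            est$intermediate$olze_triggered else NA,
          n_substitutions = length(est$substitutions),
          substitutions = paste(est$substitutions, collapse = ";"),
          note = ""
        )
      } else {
        tibble::tibble(
          subject_id = sid,
          method = c(nolla = "NOLLA", demirjian_olze = "DEMIRJIAN_OLZE",
                     atlas = "LONDON_ATLAS")[[m]],
          age_est = NA_real_, score = NA_real_, clamped = NA,
          olze_triggered = NA, n_substitutions = 0L, substitutions = "",
          note = conditionMessage(est)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
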