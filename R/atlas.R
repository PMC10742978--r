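#' Mismatch between an observed stage pattern and an atlas chart
#'
#' The dissimilarity between a dentition and an age-indexed chart is the
#' mean absolute difference of ordinal stages over the teeth the two
#' share: 0 exactly when they agree on every shared tooth.
#'
#' @param observed named integer vector of ordinal stages, names = FDI
#'   codes.
#' @param chart_pattern named integer vector for one chart, same naming.
#' @return non-negative mean absolute stage discrepancy.
#' @examples
#' atlas_mismatch(c(`11` = 3, `16` = 5, `41` = 7),
#'                c(`11` = 3, `16` = 6, `41` = 7))  # 1/3
#' @export
atlas_mismatch <- function(observed, chart_pattern) {
  shared <- intersect(names(observed), names(chart_pattern))
  if (length(shared) == 0) {
    dentage_abort("no teeth shared between observation and chart",
                  "dentage_error_incomparable")
  }
  mean(abs(as.numeric(observed[shared]) - as.numeric(chart_pattern[shared])))
}

# observed atlas pattern over the charts' teeth; right side is the
# atlas convention, so a left tooth substitutes a missing right one
atlas_observed_pattern <- function(subject_records, chart_teeth) {
  stages <- integer(0)
  subs <- character(0)
  for (fdi in chart_teeth) {
    hit <- contralateral_substitute(subject_records, fdi, "ATLAS")
    if (is.null(hit)) next
    stages[as.character(fdi)] <- as.integer(hit$stage)
    if (hit$substituted) subs <- c(subs, sub_label(fdi, hit$fdi_used))
  }
  list(stages = stages, substitutions = subs)
}

#' Estimate age by London-Atlas-style pattern matching
#'
#' Compares the observed ordinal stage pattern with every age-indexed
#' chart and assigns the chart age of the minimal mismatch; when two or
#' more charts tie for minimal mismatch (a dentition "between" figures),
#' the arithmetic mean of the tied chart ages is used.  The atlas makes
#' no distinction between the sexes.
#'
#' @param subject_records one subject's stage-record rows.
#' @param tables a `dentage_tables` object (its `atlas` component is
#'   used).
#' @return a `dentage_estimate`; `intermediate` holds the tied chart
#'   ages and the minimal mismatch score.
#' @export
estimate_london_atlas <- function(subject_records, tables) {
  at <- tables$atlas
  if (is.null(at) || nrow(at) == 0) {
    dentage_abort("table set has no atlas charts", "dentage_error_table")
  }
  chart_teeth <- sort(unique(at$fdi))
  obs <- atlas_observed_pattern(subject_records, chart_teeth)
  if (length(obs$stages) == 0) {
    dentage_abort("no atlas-scheme assessments to compare with the charts",
                  "dentage_error_estimation_failure")
  }
  chart_ages <- sort(unique(at$chart_age))
  scores <- vapply(chart_ages, function(a) {
    rows <- at[at$chart_age == a, ]
    pattern <- stats::setNames(rows$stage, as.character(rows$fdi))
    tryCatch(atlas_mismatch(obs$stages, pattern),
             dentage_error_incomparable = function(e) Inf)
  }, numeric(1))
  if (all(is.infinite(scores))) {
    dentage_abort("observation shares no teeth with any chart",
                  "dentage_error_estimation_failure")
  }
  best <- min(scores)
  tied <- chart_ages[scores <= best + 1e-9]
  new_estimate(
    method = "LONDON_ATLAS",
    age_est = mean(tied),
    intermediate = list(matched_chart_ages = tied, mismatch = best,
                        n_teeth_compared = length(obs$stages)),
    substitutions = obs$substitutions,
    clamped = FALSE
  )
}
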