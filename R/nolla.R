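#' Nolla tooth value
#'
#' Each tooth is assigned an integer calcification stage 1–10; a tooth
#' lying between two stages gains 0.2 (closer to the lower stage), 0.5
#' (midway) or 0.7 (closer to the upper stage).  A tooth between stages
#' 6 and 7 is therefore scored 6.2, 6.5 or 6.7.
#'
#' @param stage integer stage 1–10.
#' @param proximity `"exact"`, `"plus02"`, `"plus05"` or `"plus07"`;
#'   stage 10 admits only `"exact"`.
#' @return the decimal tooth value in \[1, 10\].
#' @examples
#' nolla_tooth_value(6, "plus02")  # 6.2
#' @export
nolla_tooth_value <- function(stage, proximity = "exact") {
  check_nolla_stage(stage, proximity)
  stage + nolla_proximity_value[[proximity]]
}

nolla_scope_quadrants <- function(jaw_scope) {
  switch(jaw_scope,
    mandible = list(c(left = 3L, right = 4L)),
    maxilla = list(c(left = 2L, right = 1L)),
    both = list(c(left = 3L, right = 4L), c(left = 2L, right = 1L)),
    dentage_abort(sprintf("unknown jaw_scope '%s'", jaw_scope),
                  "dentage_error_table")
  )
}

#' Sum of Nolla values over tooth pairs
#'
#' Left and right development is near-identical, so one value is
#' retained per left/right pair: the left tooth's value when it is
#' assessable, otherwise the right tooth's (recorded as a
#' substitution).  Pairs at positions 1–7 of each jaw in scope are
#' mandatory; third-molar pairs (position 8) are included only when
#' `include_third_molars` is `TRUE`.
#'
#' @param subject_records one subject's stage-record rows.
#' @param jaw_scope `"mandible"`, `"maxilla"` or `"both"`.
#' @param include_third_molars logical.
#' @return list with `sum` (decimal), `teeth_used` (tibble of
#'   `fdi, value, substituted`) and `substitutions` (character labels).
#' @export
nolla_sum <- function(subject_records, jaw_scope = "mandible",
                      include_third_molars = FALSE) {
  positions <- if (include_third_molars) 1:8 else 1:7
  used <- list()
  subs <- character(0)
  total <- 0
  for (quads in nolla_scope_quadrants(jaw_scope)) {
    for (p in positions) {
      left_fdi <- quads[["left"]] * 10L + p
      hit <- contralateral_substitute(subject_records, left_fdi, "NOLLA")
      if (is.null(hit)) {
        dentage_abort(
          sprintf("incomplete dentition: Nolla pair %d/%d has no assessable member",
                  left_fdi, contralateral(left_fdi)),
          "dentage_error_incomplete"
        )
      }
      st <- parse_nolla_stage(hit$stage)
      value <- nolla_tooth_value(st$stage, st$proximity)
      total <- total + value
      used[[length(used) + 1L]] <- tibble::tibble(
        fdi = hit$fdi_used, value = value, substituted = hit$substituted
      )
      if (hit$substituted) subs <- c(subs, sub_label(left_fdi, hit$fdi_used))
    }
  }
  list(sum = total, teeth_used = dplyr::bind_rows(used), substitutions = subs)
}

third_molar_pair_assessable <- function(subject_records, jaw_scope, scheme) {
  all(vapply(nolla_scope_quadrants(jaw_scope), function(quads) {
    !is.null(contralateral_substitute(subject_records,
                                      quads[["left"]] * 10L + 8L, scheme))
  }, logical(1)))
}

#' Estimate age with Nolla's method
#'
#' Sums one Nolla value per tooth pair within the chosen jaw scope and
#' converts the sum to age through the sex-specific Nolla table that
#' matches the scope and third-molar setting.  With
#' `include_third_molars = NULL` (the default) the third molars are
#' included exactly when every third-molar pair in scope is assessable,
#' and the matching table variant is selected automatically.
#'
#' @param subject_records one subject's stage-record rows.
#' @param tables a `dentage_tables` object.
#' @param jaw_scope `"mandible"` (default, as the method is usually
#'   read), `"maxilla"` or `"both"`.
#' @param include_third_molars logical, or `NULL` for automatic.
#' @return a `dentage_estimate` with the sum of values and teeth used in
#'   `intermediate`.
#' @export
estimate_nolla <- function(subject_records, tables, jaw_scope = "mandible",
                           include_third_molars = NULL) {
  if (is.null(include_third_molars)) {
    include_third_molars <-
      third_molar_pair_assessable(subject_records, jaw_scope, "NOLLA")
  }
  sex <- subject_records$sex[1]
  s <- nolla_sum(subject_records, jaw_scope, include_third_molars)
  tb <- nolla_table_for(tables, sex, jaw_scope, include_third_molars)
  hit <- lookup_age(tb$knots, s$sum)
  new_estimate(
    method = "NOLLA",
    age_est = hit$age,
    intermediate = list(sum_of_values = s$sum, jaw_scope = jaw_scope,
                        includes_third_molars = include_third_molars,
                        teeth_used = s$teeth_used),
    substitutions = s$substitutions,
    clamped = hit$clamped
  )
}
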