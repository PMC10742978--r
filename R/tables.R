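#' Reference table sets
#'
#' A `dentage_tables` object bundles every lookup table the three
#' engines need:
#'
#' * `nolla` — a list of sex-specific tables, each with `sex`,
#'   `jaw_scope` (`"mandible"`, `"maxilla"` or `"both"`),
#'   `includes_third_molars` and `knots`, a tibble `(sum_value, age)`
#'   mapping the summed per-pair Nolla values to age.
#' * `demirjian_scores` — per sex, a tibble `(position, stage, score)`
#'   giving the self-weighted score of each stage of the seven left
#'   mandibular teeth (position 1 central incisor ... 7 second molar).
#' * `demirjian_age` — per sex, a tibble `(score, age)` mapping the
#'   total maturity score S (0–100) to dental age.
#' * `olze` — per sex, a tibble `(stage, age)` mapping a third molar's
#'   Demirjian letter stage directly to age.
#' * `atlas` — a sex-agnostic long tibble `(chart_age, fdi, stage)` of
#'   age-indexed expected stage patterns.
#' * `provenance` — free-text source citation; mandatory, because more
#'   than one transcription of the historical tables circulates.
#'
#' `new_table_set()` assembles the object; [validate_table_set()] checks
#' every structural invariant.
#'
#' @param nolla,demirjian_scores,demirjian_age,olze,atlas,provenance
#'   components as described above.
#' @return an object of class `dentage_tables`.
#' @export
new_table_set <- function(nolla, demirjian_scores, demirjian_age, olze,
                          atlas, provenance) {
  structure(
    list(
      schema = "dentage-tables/1",
      provenance = provenance,
      nolla = nolla,
      demirjian_scores = demirjian_scores,
      demirjian_age = demirjian_age,
      olze = olze,
      atlas = tibble::as_tibble(atlas)
    ),
    class = "dentage_tables"
  )
}

#' @export
print.dentage_tables <- function(x, ...) {
  cat("<dentage_tables> schema", x$schema, "\n")
  cat("  provenance:", x$provenance, "\n")
  for (tb in x$nolla) {
    cat(sprintf("  nolla[%s, %s, third molars %s]: %d knots\n", tb$sex,
                tb$jaw_scope, ifelse(tb$includes_third_molars, "in", "out"),
                nrow(tb$knots)))
  }
  for (s in names(x$demirjian_age)) {
    cat(sprintf("  demirjian[%s]: %d score rows, %d age knots, %d Olze entries\n",
                s, nrow(x$demirjian_scores[[s]]), nrow(x$demirjian_age[[s]]),
                nrow(x$olze[[s]])))
  }
  cat(sprintf("  atlas: %d charts (%.1f-%.1f y)\n",
              length(unique(x$atlas$chart_age)), min(x$atlas$chart_age),
              max(x$atlas$chart_age)))
  invisible(x)
}

nolla_table_for <- function(tables, sex, jaw_scope, includes_third_molars) {
  for (tb in tables$nolla) {
    if (tb$sex == sex && tb$jaw_scope == jaw_scope &&
        tb$includes_third_molars == includes_third_molars) {
      return(tb)
    }
  }
  dentage_abort(
    sprintf("no Nolla table for sex=%s, jaw_scope=%s, third molars %s",
            sex, jaw_scope, ifelse(includes_third_molars, "included", "excluded")),
    "dentage_error_table"
  )
}

#' Validate a reference table set
#'
#' Checks every structural invariant: Nolla knots strictly increasing in
#' the sum of values and non-decreasing in age; Demirjian scores strictly
#' increasing along the stage order at every tooth position; maturity
#' score knots strictly increasing in S within \[0, 100\]; Olze ages
#' non-decreasing along the stage order; atlas chart ages strictly
#' increasing with 0.5–1 year steps; tables present for both sexes; a
#' non-empty provenance string.
#'
#' @param tables a `dentage_tables` object.
#' @return a character vector of violations, empty when the set is valid.
#' @export
validate_table_set <- function(tables) {
  v <- character(0)
  note <- function(...) v <<- c(v, sprintf(...))

  if (!identical(tables$schema, "dentage-tables/1")) {
    note("table set: unknown schema '%s'", tables$schema)
  }
  if (is.null(tables$provenance) || !nzchar(tables$provenance)) {
    note("table set: provenance is mandatory")
  }

  sexes_seen <- vapply(tables$nolla, function(tb) tb$sex, character(1))
  for (s in c("male", "female")) {
    if (!s %in% sexes_seen) note("nolla: no table for sex %s", s)
  }
  for (tb in tables$nolla) {
    lab <- sprintf("nolla[%s,%s,3M=%s]", tb$sex, tb$jaw_scope,
                   tb$includes_third_molars)
    k <- tb$knots
    if (nrow(k) < 2) note("%s: fewer than 2 knots", lab)
    if (is.unsorted(k$sum_value, strictly = TRUE)) {
      note("%s: knots not strictly increasing in sum_value", lab)
    }
    if (is.unsorted(k$age)) note("%s: knot ages decrease", lab)
  }

  for (s in c("male", "female")) {
    sc <- tables$demirjian_scores[[s]]
    if (is.null(sc)) {
      note("demirjian_scores: no table for sex %s", s)
    } else {
      for (p in 1:7) {
        rows <- sc[sc$position == p, ]
        if (nrow(rows) == 0) {
          note("demirjian_scores[%s]: position %d missing", s, p)
          next
        }
        ord <- order(demirjian_stage_index(rows$stage))
        if (is.unsorted(rows$score[ord], strictly = TRUE)) {
          note("demirjian_scores[%s]: scores not strictly increasing at position %d",
               s, p)
        }
      }
    }
    ag <- tables$demirjian_age[[s]]
    if (is.null(ag) || nrow(ag) < 2) {
      note("demirjian_age[%s]: missing or fewer than 2 knots", s)
    } else {
      if (is.unsorted(ag$score, strictly = TRUE)) {
        note("demirjian_age[%s]: knots not strictly increasing in score", s)
      }
      if (is.unsorted(ag$age)) note("demirjian_age[%s]: knot ages decrease", s)
      if (any(ag$score < 0 | ag$score > 100)) {
        note("demirjian_age[%s]: maturity score outside [0, 100]", s)
      }
    }
    ol <- tables$olze[[s]]
    if (is.null(ol) || nrow(ol) == 0) {
      note("olze[%s]: missing", s)
    } else {
      ord <- order(demirjian_stage_index(ol$stage))
      if (is.unsorted(ol$age[ord])) {
        note("olze[%s]: ages decrease along the stage order", s)
      }
    }
  }

  at <- tables$atlas
  if (is.null(at) || nrow(at) == 0) {
    note("atlas: no charts")
  } else {
    ages <- sort(unique(at$chart_age))
    if (length(ages) < 2) note("atlas: fewer than 2 charts")
    steps <- diff(ages)
    if (any(steps < 0.5 - 1e-9 | steps > 1.0 + 1e-9)) {
      note("atlas: consecutive chart ages must differ by 0.5-1.0 years")
    }
    if (!all(is_valid_fdi(at$fdi))) note("atlas: invalid FDI code in a chart")
    if (any(at$stage < 1)) note("atlas: ordinal stages must be >= 1")
  }

  v
}
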