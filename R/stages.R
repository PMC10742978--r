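#' Staging schemes and stage tokens
#'
#' Three staging schemes are supported, one per estimation method:
#'
#' * `"NOLLA"` — integer calcification stages 1–10, refined by a
#'   proximity qualifier when a tooth lies between two stages: `plus02`
#'   (closer to the lower stage, scored +0.2), `plus05` (midway, +0.5),
#'   `plus07` (closer to the upper stage, +0.7).  Tokens look like
#'   `"6"`, `"6.2"`, `"6.5"`, `"6.7"`.
#' * `"DEMIRJIAN"` — letter stages `A`–`H` plus the token `"0"` for a
#'   tooth whose calcification has not started (crypt only).
#' * `"ATLAS"` — a positive ordinal stage index on the chart set's own
#'   grid.
#'
#' @name staging
NULL

dentage_schemes <- c("NOLLA", "DEMIRJIAN", "ATLAS")

nolla_proximity_levels <- c("exact", "plus02", "plus05", "plus07")
nolla_proximity_value <- c(exact = 0, plus02 = 0.2, plus05 = 0.5, plus07 = 0.7)

demirjian_stage_levels <- c("0", LETTERS[1:8])

#' Parse a Nolla stage token
#'
#' @param token character like `"6"`, `"6.2"`, `"6.5"` or `"6.7"`.
#' @return a list with integer `stage` (1–10) and `proximity`
#'   (one of `"exact"`, `"plus02"`, `"plus05"`, `"plus07"`).
#' @examples
#' parse_nolla_stage("6.2")
#' @export
parse_nolla_stage <- function(token) {
  token <- as.character(token)
  m <- regmatches(token, regexec("^([0-9]+)(?:\\.([257]))?$", token))[[1]]
  if (length(m) == 0) {
    dentage_abort(sprintf("invalid Nolla stage token '%s'", token),
                  "dentage_error_stage")
  }
  stage <- as.integer(m[2])
  proximity <- switch(ifelse(m[3] == "", "0", m[3]),
                      "0" = "exact", "2" = "plus02",
                      "5" = "plus05", "7" = "plus07")
  check_nolla_stage(stage, proximity)
  list(stage = stage, proximity = proximity)
}

check_nolla_stage <- function(stage, proximity) {
  if (is.na(stage) || stage < 1L || stage > 10L) {
    dentage_abort(sprintf("Nolla stage %s outside 1-10", stage),
                  "dentage_error_stage")
  }
  if (!proximity %in% nolla_proximity_levels) {
    dentage_abort(sprintf("unknown Nolla proximity '%s'", proximity),
                  "dentage_error_stage")
  }
  if (stage == 10L && proximity != "exact") {
    dentage_abort("Nolla stage 10 admits no proximity qualifier (no stage 11)",
                  "dentage_error_stage")
  }
  invisible(TRUE)
}

format_nolla_stage <- function(stage, proximity = "exact") {
  check_nolla_stage(stage, proximity)
  add <- nolla_proximity_value[[proximity]]
  if (add == 0) as.character(stage) else sprintf("%d.%d", stage, round(add * 10))
}

#' Position of a Demirjian letter stage in the developmental order
#' ("0" = 0, A = 1, ..., H = 8).
#' @param token character stage token.
#' @return integer index, or an error for an unknown token.
#' @export
demirjian_stage_index <- function(token) {
  idx <- match(as.character(token), demirjian_stage_levels)
  if (anyNA(idx)) {
    dentage_abort(
      sprintf("invalid Demirjian stage token '%s'",
              paste(token[is.na(idx)], collapse = ", ")),
      "dentage_error_stage"
    )
  }
  idx - 1L
}

# TRUE/FALSE without raising, used by record validation
is_valid_stage_token <- function(scheme, token) {
  vapply(seq_along(token), function(i) {
    tk <- token[i]
    if (is.na(tk)) return(FALSE)
    switch(scheme[i],
      NOLLA = tryCatch({ parse_nolla_stage(tk); TRUE },
                       dentage_error = function(e) FALSE),
      DEMIRJIAN = tk %in% demirjian_stage_levels,
      ATLAS = grepl("^[0-9]+$", tk) && as.integer(tk) >= 1L,
      FALSE
    )
  }, logical(1))
}
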