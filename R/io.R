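#' Read and write reference table sets
#'
#' Table sets travel as a single JSON document, schema-versioned
#' `"dentage-tables/1"`; numbers are written at full precision so a
#' write/read round trip reproduces the set field-for-field.
#'
#' @param tables a `dentage_tables` object.
#' @param path file path of the JSON document.
#' @return `read_table_set()` returns a `dentage_tables` object;
#'   `write_table_set()` returns `path` invisibly.
#' @export
write_table_set <- function(tables, path) {
  x <- unclass(tables)
  x$atlas <- as.list(x$atlas)
  x$nolla <- lapply(x$nolla, function(tb) {
    tb$knots <- as.list(tb$knots)
    tb
  })
  for (comp in c("demirjian_scores", "demirjian_age", "olze")) {
    x[[comp]] <- lapply(x[[comp]], as.list)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

json_tbl <- function(cols, int_cols = character(0), chr_cols = character(0)) {
  out <- lapply(names(cols), function(nm) {
    v <- unlist(cols[[nm]], use.names = FALSE)
    if (nm %in% int_cols) as.integer(v)
    else if (nm %in% chr_cols) as.character(v)
    else as.numeric(v)
  })
  names(out) <- names(cols)
  tibble::as_tibble(out)
}

#' @rdname write_table_set
#' @export
read_table_set <- function(path) {
  if (!file.exists(path)) {
    dentage_abort(sprintf("table file not found: %s", path), "dentage_error_io")
  }
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    dentage_abort(sprintf("cannot parse table file %s: %s",
                                          path, conditionMessage(e)),
                                  "dentage_error_parse")
                  })
  if (!identical(raw$schema, "dentage-tables/1")) {
    dentage_abort(sprintf("%s: unsupported table schema '%s'", path,
                          raw$schema), "dentage_error_parse")
  }
  per_sex <- function(component, ...) {
    lapply(raw[[component]], json_tbl, ...)
  }
  nolla <- lapply(raw$nolla, function(tb) {
    list(sex = tb$sex, jaw_scope = tb$jaw_scope,
         includes_third_molars = isTRUE(tb$includes_third_molars),
         knots = json_tbl(tb$knots))
  })
  new_table_set(
    nolla = nolla,
    demirjian_scores = per_sex("demirjian_scores", int_cols = "position",
                               chr_cols = "stage"),
    demirjian_age = per_sex("demirjian_age"),
    olze = per_sex("olze", chr_cols = "stage"),
    atlas = json_tbl(raw$atlas, int_cols = c("fdi", "stage")),
    provenance = raw$provenance
  )
}

#' Read and write stage-record files
#'
#' The delimited format has one row per (subject, tooth, scheme) with
#' columns `subject_id, sex, age_years, age_months, fdi, scheme, stage,
#' present`; chronological age is assembled as `age_years + age_months/12`
#' (one-month precision).  Malformed rows are reported with their line
#' numbers.  A one-subject-per-document JSON variant is available through
#' `read_subject_json()` / `write_subject_json()`.
#'
#' @param path file path.
#' @param records a validated stage-record tibble (see
#'   [validate_records()]).
#' @return `read_records()` returns a validated stage-record tibble.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    dentage_abort(sprintf("record file not found: %s", path), "dentage_error_io")
  }
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  needed <- c("subject_id", "sex", "age_years", "age_months", "fdi",
              "scheme", "stage", "present")
  if (!all(needed %in% names(df))) {
    dentage_abort(sprintf("%s: missing column(s) %s", path,
                          paste(setdiff(needed, names(df)), collapse = ", ")),
                  "dentage_error_parse")
  }
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  num_or_bad <- function(x) suppressWarnings(as.numeric(x))
  yrs <- num_or_bad(df$age_years)
  mos <- num_or_bad(df$age_months)
  fdi <- num_or_bad(df$fdi)
  bad <- is.na(yrs) | is.na(mos) | mos < 0 | mos > 11 |
    !is_valid_fdi(fdi) | !df$scheme %in% dentage_schemes
  stage <- ifelse(df$stage == "" | toupper(df$stage) == "NA", NA_character_,
                  df$stage)
  present <- toupper(df$present) %in% c("TRUE", "T", "1", "YES")
  staged <- present & !is.na(stage)
  bad[staged][!is_valid_stage_token(df$scheme[staged], stage[staged])] <- TRUE
  if (any(bad)) {
    dentage_abort(sprintf("%s: malformed row(s) at line(s) %s", path,
                          paste(line_no[bad], collapse = ", ")),
                  "dentage_error_parse")
  }
  records <- tibble::tibble(
    subject_id = df$subject_id,
    sex = df$sex,
    age_true = yrs + mos / 12,
    fdi = as.integer(fdi),
    scheme = df$scheme,
    stage = ifelse(present, stage, NA_character_),
    present = present
  )
  validate_records(records)
  records
}

split_age <- function(age_true) {
  months_total <- round(age_true * 12)
  list(years = months_total %/% 12, months = months_total %% 12)
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  validate_records(records)
  a <- split_age(records$age_true)
  out <- data.frame(
    subject_id = records$subject_id,
    sex = records$sex,
    age_years = a$years,
    age_months = a$months,
    fdi = records$fdi,
    scheme = records$scheme,
    stage = ifelse(is.na(records$stage), "", records$stage),
    present = records$present
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_records
#' @export
read_subject_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(raw$assessments, function(a) {
    tibble::tibble(
      subject_id = raw$subject_id,
      sex = raw$sex,
      age_true = as.numeric(raw$age_years) + as.numeric(raw$age_months) / 12,
      fdi = as.integer(a$fdi),
      scheme = a$scheme,
      stage = if (is.null(a$stage)) NA_character_ else as.character(a$stage),
      present = isTRUE(a$present)
    )
  })
  records <- dplyr::bind_rows(rows)
  validate_records(records)
  records
}

#' @rdname read_records
#' @export
write_subject_json <- function(records, path) {
  validate_records(records)
  if (length(unique(records$subject_id)) != 1) {
    dentage_abort("write_subject_json() takes exactly one subject",
                  "dentage_error_io")
  }
  a <- split_age(records$age_true[1])
  doc <- list(
    subject_id = records$subject_id[1],
    sex = records$sex[1],
    age_years = a$years[1],
    age_months = a$months[1],
    assessments = lapply(seq_len(nrow(records)), function(i) {
      list(fdi = records$fdi[i], scheme = records$scheme[i],
           stage = if (is.na(records$stage[i])) NULL else records$stage[i],
           present = records$present[i])
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
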