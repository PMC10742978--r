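#' FDI two-digit tooth notation
#'
#' Teeth are identified by the FDI (Federation Dentaire Internationale)
#' two-digit code: the first digit is the quadrant (1 upper right,
#' 2 upper left, 3 lower left, 4 lower right), the second the position
#' from the midline (1 central incisor ... 8 third molar).  Tooth 38 is
#' the lower-left third molar.
#'
#' @param fdi integer vector of two-digit FDI codes.
#' @return `is_valid_fdi()` and the `is_*` predicates return logicals;
#'   `contralateral()`, `pair_partner()` and `antagonist()` return FDI codes.
#' @examples
#' is_valid_fdi(38)       # TRUE
#' contralateral(38)      # 48, the lower-right third molar
#' is_mandibular(38)      # TRUE
#' @name fdi
NULL

fdi_quadrant <- function(fdi) fdi %/% 10L
fdi_position <- function(fdi) fdi %% 10L

#' @rdname fdi
#' @export
is_valid_fdi <- function(fdi) {
  !is.na(fdi) & fdi == as.integer(fdi) &
    fdi_quadrant(fdi) %in% 1:4 & fdi_position(fdi) %in% 1:8
}

stopifnot_fdi <- function(fdi) {
  bad <- fdi[!is_valid_fdi(fdi)]
  if (length(bad) > 0) {
    dentage_abort(
      sprintf("invalid FDI tooth code(s): %s", paste(bad, collapse = ", ")),
      "dentage_error_fdi"
    )
  }
  as.integer(fdi)
}

#' @rdname fdi
#' @export
is_mandibular <- function(fdi) fdi_quadrant(stopifnot_fdi(fdi)) %in% c(3L, 4L)

#' @rdname fdi
#' @export
is_maxillary <- function(fdi) !is_mandibular(fdi)

#' @rdname fdi
#' @export
is_left <- function(fdi) fdi_quadrant(stopifnot_fdi(fdi)) %in% c(2L, 3L)

#' @rdname fdi
#' @export
is_right <- function(fdi) !is_left(fdi)

#' @rdname fdi
#' @export
is_third_molar <- function(fdi) fdi_position(stopifnot_fdi(fdi)) == 8L

#' Mirror a tooth across the midline (same jaw, other side).
#' An involution: `contralateral(contralateral(t)) == t`.
#' @rdname fdi
#' @export
contralateral <- function(fdi) {
  fdi <- stopifnot_fdi(fdi)
  mirror <- c(2L, 1L, 4L, 3L)
  mirror[fdi_quadrant(fdi)] * 10L + fdi_position(fdi)
}

#' The other member of a left/right tooth pair ("only one value is
#' retained per pair of teeth" in Nolla scoring); identical to
#' [contralateral()].
#' @rdname fdi
#' @export
pair_partner <- function(fdi) contralateral(fdi)

#' The opposing tooth in the other jaw, same side and position.
#' Also an involution.
#' @rdname fdi
#' @export
antagonist <- function(fdi) {
  fdi <- stopifnot_fdi(fdi)
  flip <- c(4L, 3L, 2L, 1L)
  flip[fdi_quadrant(fdi)] * 10L + fdi_position(fdi)
}

all_fdi_codes <- function() {
  as.integer(outer(1:4 * 10L, 1:8, `+`))
}
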