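#' Age lookup in a monotone knot table
#'
#' All table-to-age conversions share one rule: an abscissa that hits a
#' knot returns that knot's age exactly; a value strictly between two
#' knots is linearly interpolated (which reproduces the conventional
#' "average the two ages" rule at the exact midpoint); a value outside
#' the tabulated range is clamped to the nearest boundary age and
#' flagged, since cohorts routinely extend past a method's table ceiling.
#'
#' @param knots tibble/data.frame with the abscissa in its first column
#'   (strictly increasing) and `age` in its second.
#' @param x the value to look up.
#' @return list with `age` (years) and `clamped` (logical).
#' @examples
#' lookup_age(data.frame(sum_value = c(50, 54), age = c(10, 11)), 52)
#' @export
lookup_age <- function(knots, x) {
  if (is.null(knots) || nrow(knots) < 2) {
    dentage_abort("lookup table needs at least 2 knots", "dentage_error_table")
  }
  xs <- knots[[1]]
  ages <- knots[["age"]]
  if (is.unsorted(xs, strictly = TRUE)) {
    dentage_abort("lookup table knots must be strictly increasing",
                  "dentage_error_table")
  }
  clamped <- x < xs[1] || x > xs[length(xs)]
  hit <- which(xs == x)
  age <- if (length(hit) == 1) {
    ages[hit]  # exact knot: no interpolation arithmetic, no fp drift
  } else {
    stats::approx(xs, ages, xout = x, rule = 2)$y
  }
  list(age = age, clamped = clamped)
}

new_estimate <- function(method, age_est, intermediate, substitutions,
                         clamped) {
  structure(
    list(method = method, age_est = age_est, intermediate = intermediate,
         substitutions = substitutions, clamped = clamped),
    class = "dentage_estimate"
  )
}

#' @export
print.dentage_estimate <- function(x, ...) {
  cat(sprintf("<dentage_estimate> %s: %.2f years%s\n", x$method, x$age_est,
              if (x$clamped) " (clamped to table boundary)" else ""))
  if (length(x$substitutions) > 0) {
    cat("  contralateral substitutions:",
        paste(x$substitutions, collapse = ", "), "\n")
  }
  keys <- names(x$intermediate)
  flat <- vapply(keys, function(k) paste(format(x$intermediate[[k]]),
                                         collapse = ","), character(1))
  cat(" ", paste(sprintf("%s=%s", keys, flat), collapse = "; "), "\n")
  invisible(x)
}

sub_label <- function(wanted, used) sprintf("%d<-%d", wanted, used)
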