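#' Published per-age accuracy of the three methods
#'
#' Per-age-category accuracy summaries reported by a published
#' comparative evaluation of the Nolla, Demirjian+Olze and London Atlas
#' methods on a multiethnic hospital sample of 324 subjects aged 4–20
#' (156 males, 168 females).  `by_age` holds, for each age category,
#' the subject count and each method's mean signed error and mean
#' absolute error in years; `rates` holds the corresponding
#' correct-estimation rates (percent) within 1- and 2-year margins.
#' Only the per-age rows are shipped; the study's "Total" rows are
#' count-weighted means of these and can be recomputed with
#' [weighted_totals()].
#'
#' Note the published rate table's own denominators at ages 10 and 16
#' differ by one subject from the count column, so recomputed rate
#' totals match the printed ones only to about 0.1 percentage points.
#'
#' @return list of tibbles `by_age` and `rates`.
#' @export
load_reference_accuracy <- function() {
  path <- function(f) system.file("extdata", f, package = "dentage",
                                  mustWork = TRUE)
  by_age <- tibble::as_tibble(
    utils::read.csv(path("reference_study_table1.csv")))
  rates <- tibble::as_tibble(
    utils::read.csv(path("reference_study_table2.csv")))
  list(by_age = by_age, rates = rates)
}
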