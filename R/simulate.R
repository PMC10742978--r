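#' Maturation model for synthetic dentitions
#'
#' A deliberately simple model of permanent-tooth calcification: each
#' tooth type develops across a fixed age window `[t_start, t_end]`
#' (years), inside which its stages are entered at equally spaced ages —
#' 10 Nolla stages, 8 Demirjian letter stages (token "0" before
#' `t_start`), and `n_atlas_stages` ordinal atlas stages.  One latent
#' maturation age per subject (chronological age plus a normally
#' distributed tempo shift) drives all three schemes, so methods are
#' correlated across schemes as they are in real dentitions.  Females
#' mature `sex_offset` years ahead of males (windows shifted by ±
#' `sex_offset / 2`); third molars develop late (8–21 years), which is
#' what makes them informative near the age of majority.
#'
#' Default windows are realistic for permanent teeth (first molars
#' begin calcifying around birth, second molars complete their roots in
#' the mid-teens, third molars around 21); defaults for the tempo SD
#' (0.7 y), the ±1-stage mis-reading probability (0.05) and the
#' unobservable-tooth probability (0.03) are plausible single-examiner
#' panoramic-radiograph conditions.
#'
#' @param windows tibble `jaw, position, t_start, t_end` covering
#'   positions 1–8 of both jaws.
#' @param sex_offset female-minus-male maturation lead, years.
#' @param individual_effect_sd SD of the per-subject tempo shift, years.
#' @param observation_noise probability a tooth's stage is mis-read by
#'   one stage (split evenly up/down, truncated at scheme boundaries);
#'   must be below 0.5.
#' @param missing_prob probability a tooth is unobservable on the image.
#' @param n_atlas_stages ordinal resolution of the atlas scheme.
#' @return an object of class `maturation_model`.
#' @export
maturation_model <- function(windows = default_tooth_windows(),
                             sex_offset = 0.5,
                             individual_effect_sd = 0.7,
                             observation_noise = 0.05,
                             missing_prob = 0.03,
                             n_atlas_stages = 14L) {
  windows <- tibble::as_tibble(windows)
  needed <- expand.grid(jaw = c("mandible", "maxilla"), position = 1:8)
  key <- paste(windows$jaw, windows$position)
  if (!all(paste(needed$jaw, needed$position) %in% key)) {
    dentage_abort("windows must cover positions 1-8 of both jaws",
                  "dentage_error_model")
  }
  if (any(windows$t_start <= 0) || any(windows$t_end <= windows$t_start)) {
    dentage_abort("tooth windows need 0 < t_start < t_end",
                  "dentage_error_model")
  }
  if (individual_effect_sd < 0) {
    dentage_abort("individual_effect_sd must be >= 0", "dentage_error_model")
  }
  if (observation_noise < 0 || observation_noise >= 0.5) {
    dentage_abort("observation_noise must lie in [0, 0.5)",
                  "dentage_error_model")
  }
  if (missing_prob < 0 || missing_prob >= 1) {
    dentage_abort("missing_prob must lie in [0, 1)", "dentage_error_model")
  }
  structure(
    list(windows = windows, sex_offset = sex_offset,
         individual_effect_sd = individual_effect_sd,
         observation_noise = observation_noise,
         missing_prob = missing_prob,
         n_atlas_stages = as.integer(n_atlas_stages)),
    class = "maturation_model"
  )
}

#' @rdname maturation_model
#' @export
default_tooth_windows <- function() {
  mand <- tibble::tibble(
    jaw = "mandible",
    position = 1:8,
    t_start = c(0.6, 0.9, 0.8, 1.8, 2.5, 0.6, 2.7, 8.0),
    t_end = c(7.0, 8.0, 12.0, 12.5, 13.5, 9.0, 16.0, 21.0)
  )
  max <- mand
  max$jaw <- "maxilla"
  max$t_start <- max$t_start + 0.3
  max$t_end <- max$t_end + 0.3
  dplyr::bind_rows(mand, max)
}

#' @export
print.maturation_model <- function(x, ...) {
  cat(sprintf(paste0("<maturation_model> tempo sd %.2f y, mis-stage p %.2f, ",
                     "missing p %.2f, sex offset %.2f y\n"),
              x$individual_effect_sd, x$observation_noise, x$missing_prob,
              x$sex_offset))
  invisible(x)
}

# window for one tooth under one sex (NULL sex = sex-agnostic midline)
tooth_window <- function(model, jaw, position, sex = NULL) {
  w <- model$windows[model$windows$jaw == jaw &
                       model$windows$position == position, ]
  shift <- if (is.null(sex)) 0
           else if (sex == "female") -model$sex_offset / 2
           else model$sex_offset / 2
  c(start = w$t_start[1] + shift, end = w$t_end[1] + shift)
}

# index of the highest of K equally spaced stage-entry ages reached by
# `latent`; first entry at `start`, last at `end`; floor = 0 lets a
# scheme (Demirjian) express "not started"
stage_count <- function(latent, start, end, K, floor_stage = 1L) {
  step <- (end - start) / (K - 1)
  idx <- floor((latent - start) / step) + 1
  as.integer(pmax(floor_stage, pmin(K, idx)))
}

# noise-free stage tokens of every modelled tooth at one latent age
latent_stages <- function(model, latent, sex = NULL) {
  rows <- list()
  for (i in seq_len(nrow(model$windows))) {
    jaw <- model$windows$jaw[i]
    pos <- model$windows$position[i]
    w <- tooth_window(model, jaw, pos, sex)
    step10 <- (w[["end"]] - w[["start"]]) / 9
    nolla_idx <- stage_count(latent, w[["start"]], w[["end"]], 10L)
    frac <- (latent - (w[["start"]] + (nolla_idx - 1) * step10)) / step10
    prox <- if (nolla_idx == 10L || frac < 0.1) "exact"
            else if (frac < 0.4) "plus02"
            else if (frac < 0.6) "plus05"
            else "plus07"
    dem_idx <- stage_count(latent, w[["start"]], w[["end"]], 8L,
                           floor_stage = 0L)
    rows[[i]] <- tibble::tibble(
      jaw = jaw, position = pos,
      nolla_stage = nolla_idx, nolla_proximity = prox,
      demirjian_index = dem_idx,
      atlas_stage = stage_count(latent, w[["start"]], w[["end"]],
                                model$n_atlas_stages)
    )
  }
  dplyr::bind_rows(rows)
}

#' Cohort composition specification
#'
#' Defaults emulate the reference study sample: 324 subjects aged 4–20,
#' with the published per-age-category counts and 168 females / 156
#' males.  Females are allotted to categories by largest-remainder
#' apportionment of the overall female share, so every (category, sex)
#' cell count is deterministic.  Within a category, ages are uniform on
#' the one-month grid `k + {0..11}/12`.
#'
#' @param counts named integer vector, subjects per age category.
#' @param n_female total number of females.
#' @param seed default RNG seed used by [simulate_cohort()].
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(counts = study_category_counts(),
                        n_female = 168L, seed = NULL) {
  if (any(counts < 0) || sum(counts) == 0) {
    dentage_abort("category counts must be >= 0 and sum > 0",
                  "dentage_error_model")
  }
  if (n_female < 0 || n_female > sum(counts)) {
    dentage_abort("n_female must lie in [0, total]", "dentage_error_model")
  }
  if (is.null(names(counts))) {
    dentage_abort("counts must be named by age category", "dentage_error_model")
  }
  structure(
    list(counts = counts, n_female = as.integer(n_female), seed = seed),
    class = "cohort_spec"
  )
}

#' Per-age-category subject counts of the reference study sample
#' (324 subjects, categories 4–20).
#' @return named integer vector.
#' @export
study_category_counts <- function() {
  stats::setNames(
    c(7L, 26L, 18L, 18L, 14L, 16L, 20L, 20L, 19L, 20L, 21L, 20L, 20L,
      24L, 21L, 20L, 20L),
    as.character(4:20)
  )
}

# largest-remainder apportionment of the female total across categories
allocate_females <- function(counts, n_female) {
  quota <- counts * n_female / sum(counts)
  base <- pmin(floor(quota), counts)
  left <- n_female - sum(base)
  frac <- quota - floor(quota)
  ord <- order(frac, decreasing = TRUE)
  i <- 1
  while (left > 0) {
    k <- ord[(i - 1) %% length(ord) + 1]
    if (base[k] < counts[k]) {
      base[k] <- base[k] + 1
      left <- left - 1
    }
    i <- i + 1
  }
  as.integer(base)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

nudge_stage <- function(idx, lo, hi, flip, up) {
  out <- ifelse(flip, idx + ifelse(up, 1L, -1L), idx)
  pmax(lo, pmin(hi, out))
}

#' Simulate a staged dentition cohort
#'
#' Draws the requested number of subjects per (age category, sex) cell,
#' gives each a latent maturation age (true age + tempo shift), stages
#' every modelled tooth in all three schemes from that one latent
#' state, then applies symmetric ±1-stage observation noise and random
#' tooth missingness.  Nolla and Demirjian stages are emitted for both
#' mandibular quadrants (teeth 31–38 and 41–48, so contralateral
#' substitution is exercised), atlas stages for all four quadrants.
#'
#' @param spec a [cohort_spec()].
#' @param model a [maturation_model()].
#' @param seed integer seed; defaults to the spec's.
#' @return a validated stage-record tibble.
#' @export
simulate_cohort <- function(spec, model, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "maturation_model"))
  n_f <- allocate_females(spec$counts, spec$n_female)
  with_seed(seed, {
    subjects <- list()
    idx <- 0L
    for (j in seq_along(spec$counts)) {
      k <- as.numeric(names(spec$counts)[j])
      n_k <- spec$counts[[j]]
      if (n_k == 0) next
      sexes <- c(rep("female", n_f[j]), rep("male", n_k - n_f[j]))
      for (s in sexes) {
        idx <- idx + 1L
        subjects[[idx]] <- tibble::tibble(
          subject_id = sprintf("S%04d", idx),
          sex = s,
          age_true = k + sample(0:11, 1) / 12,
          shift = stats::rnorm(1, 0, model$individual_effect_sd)
        )
      }
    }
    subjects <- dplyr::bind_rows(subjects)

    rows <- vector("list", nrow(subjects))
    for (i in seq_len(nrow(subjects))) {
      subj <- subjects[i, ]
      latent <- subj$age_true + subj$shift
      st <- latent_stages(model, latent, subj$sex)

      mand <- st[st$jaw == "mandible", ]
      quadrants <- list(NOLLA = c(3L, 4L), DEMIRJIAN = c(3L, 4L),
                        ATLAS = c(1L, 2L, 3L, 4L))
      missing_fdi <- all_fdi_codes()[
        stats::runif(32) < model$missing_prob]

      scheme_rows <- list()
      for (scheme in names(quadrants)) {
        for (q in quadrants[[scheme]]) {
          src <- if (q %in% c(3L, 4L)) mand else st[st$jaw == "maxilla", ]
          n <- nrow(src)
          flip <- stats::runif(n) < model$observation_noise
          up <- stats::runif(n) < 0.5
          token <- switch(scheme,
            NOLLA = {
              s10 <- nudge_stage(src$nolla_stage, 1L, 10L, flip, up)
              prox <- ifelse(flip | s10 == 10L, "exact", src$nolla_proximity)
              vapply(seq_len(n), function(r)
                format_nolla_stage(s10[r], prox[r]), character(1))
            },
            DEMIRJIAN = demirjian_stage_levels[
              nudge_stage(src$demirjian_index, 0L, 8L, flip, up) + 1L],
            ATLAS = as.character(
              nudge_stage(src$atlas_stage, 1L, model$n_atlas_stages, flip, up))
          )
          fdi <- q * 10L + src$position
          miss <- fdi %in% missing_fdi
          scheme_rows[[length(scheme_rows) + 1L]] <- tibble::tibble(
            subject_id = subj$subject_id, sex = subj$sex,
            age_true = subj$age_true, fdi = fdi, scheme = scheme,
            stage = ifelse(miss, NA_character_, token),
            present = !miss
          )
        }
      }
      rows[[i]] <- dplyr::bind_rows(scheme_rows)
    }
    records <- dplyr::bind_rows(rows)
    validate_records(records)
    records
  })
}

#' Derive reference tables consistent with a maturation model
#'
#' Evaluates the model's noise-free median trajectory on an age grid
#' and builds every lookup table from it, so estimation against these
#' tables inverts the generating process up to the tables' resolution:
#' Nolla mandibular knot tables (with and without third molars, per
#' sex), Demirjian self-weighted scores (equal weights scaled so the
#' maturity score tops out at 100), maturity-score-to-age knots
#' tabulated only up to `demirjian_max_age` (mirroring the real
#' tables' 16-year ceiling), the Olze third-molar stage ages, and
#' sex-agnostic atlas charts at `atlas_step` resolution.
#'
#' @param model a [maturation_model()]; its noise parameters are
#'   ignored (tables describe the median trajectory).
#' @param age_grid ages (years) at which the trajectory is evaluated.
#' @param demirjian_max_age ceiling of the maturity-score age table.
#' @param atlas_step chart spacing in years (0.5–1.0).
#' @param atlas_range age span of the chart set.
#' @return a `dentage_tables` object that passes [validate_table_set()].
#' @export
derive_tables <- function(model, age_grid = seq(2, 23, by = 0.1),
                          demirjian_max_age = 16.5, atlas_step = 0.5,
                          atlas_range = c(3.5, 23)) {
  stopifnot(inherits(model, "maturation_model"))
  nolla <- list()
  demirjian_age <- list()
  olze <- list()
  for (sex in c("male", "female")) {
    stage_grid <- lapply(age_grid, latent_stages, model = model, sex = sex)
    mand <- lapply(stage_grid, function(st) st[st$jaw == "mandible", ])

    for (inc3m in c(FALSE, TRUE)) {
      pos <- if (inc3m) 1:8 else 1:7
      sums <- vapply(mand, function(st) {
        s <- st[st$position %in% pos, ]
        sum(s$nolla_stage + nolla_proximity_value[s$nolla_proximity])
      }, numeric(1))
      agg <- stats::aggregate(age_grid, by = list(sum_value = sums),
                              FUN = mean)
      nolla[[length(nolla) + 1L]] <- list(
        sex = sex, jaw_scope = "mandible", includes_third_molars = inc3m,
        knots = tibble::tibble(sum_value = agg$sum_value, age = agg$x)
      )
    }

    weight <- 100 / 56  # 7 teeth x 8 stages -> S caps at 100
    keep <- age_grid <= demirjian_max_age
    scores <- vapply(mand[keep], function(st) {
      sum(st$demirjian_index[st$position %in% 1:7]) * weight
    }, numeric(1))
    agg <- stats::aggregate(age_grid[keep], by = list(score = scores),
                            FUN = mean)
    demirjian_age[[sex]] <- tibble::tibble(score = agg$score, age = agg$x)

    m3 <- vapply(mand, function(st)
      st$demirjian_index[st$position == 8L], integer(1))
    staged <- m3 > 0L
    agg <- stats::aggregate(age_grid[staged],
                            by = list(idx = m3[staged]), FUN = mean)
    olze[[sex]] <- tibble::tibble(
      stage = demirjian_stage_levels[agg$idx + 1L], age = agg$x)
  }

  demirjian_scores <- list()
  for (sex in c("male", "female")) {
    grid <- expand.grid(position = 1:7, stage = demirjian_stage_levels,
                        stringsAsFactors = FALSE)
    demirjian_scores[[sex]] <- tibble::tibble(
      position = as.integer(grid$position),
      stage = grid$stage,
      score = demirjian_stage_index(grid$stage) * 100 / 56
    )
  }

  chart_ages <- seq(atlas_range[1], atlas_range[2], by = atlas_step)
  # charts follow the atlas convention of depicting the right side
  # (quadrants 1 and 4)
  atlas <- dplyr::bind_rows(lapply(chart_ages, function(a) {
    st <- latent_stages(model, a, sex = NULL)
    tibble::tibble(
      chart_age = a,
      fdi = ifelse(st$jaw == "maxilla", 10L, 40L) + st$position,
      stage = st$atlas_stage
    )
  }))

  new_table_set(
    nolla = nolla,
    demirjian_scores = demirjian_scores,
    demirjian_age = demirjian_age,
    olze = olze,
    atlas = atlas,
    provenance = paste("synthetic tables derived from the dentage",
                       "maturation model; not a transcription of any",
                       "published table")
  )
}

#' Shift a model to create a known estimation bias
#'
#' Advancing every stage-entry age by `bias_years` (windows shifted
#' earlier) makes dentitions look more mature than the unshifted model
#' expects, so estimation against tables derived from the *unshifted*
#' model overestimates age by approximately `bias_years`.
#'
#' @param model a [maturation_model()].
#' @param bias_years years of overestimation to induce (may be
#'   negative for underestimation).
#' @return a new `maturation_model`.
#' @export
bias_scenario <- function(model, bias_years) {
  w <- model$windows
  w$t_start <- w$t_start - bias_years
  w$t_end <- w$t_end - bias_years
  if (any(w$t_start <= 0)) {
    dentage_abort("bias shift makes a stage-entry age non-positive",
                  "dentage_error_model")
  }
  out <- model
  out$windows <- w
  out
}
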