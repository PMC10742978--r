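---
title: "Dental age estimation: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dental age estimation: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentage)
```

## The problem

Estimating the chronological age of a living person from a panoramic
dental radiograph is a routine task in forensic odontology, most
prominently for migrants without identity documents, where the legal
question is usually whether the person is a minor.  Tooth
calcification is preferred over eruption as the biological signal
because it is a continuous process spanning two decades and is
relatively robust to nutrition and local conditions.

`dentage` implements three classical, table-driven estimation methods
over per-tooth developmental-stage records, together with the
evaluation pipeline used to quantify how accurate such methods are
against known ages, and a synthetic cohort generator that makes the
whole system testable end to end without radiographs.  The package
never touches images: stages arrive pre-read by a human examiner (or
an upstream tool) in tidy delimited text, one row per (subject, tooth,
scheme), with teeth in FDI two-digit notation.

## The three estimation engines

**Nolla.** Every permanent tooth is assigned a calcification stage 1–10;
a tooth between stages gains +0.2, +0.5 or +0.7 depending on which
neighbouring stage it is closer to.  We encode this as an integer stage
plus a proximity qualifier (`exact`, `plus02`, `plus05`, `plus07`), so
invalid readings like 6.3 are unrepresentable.  Left/right development
is near-identical, so one value is retained per pair (the left tooth by
convention, its contralateral partner as a recorded substitution).  The
per-pair values are summed within a jaw scope (mandible by default) and
the sum is converted to age through a sex-specific knot table; variants
with and without third molars exist, and the engine auto-selects the
third-molar variant exactly when the third-molar pair is assessable.

**Demirjian + Olze.** The seven left mandibular teeth are staged A–H
("0" before calcification starts); a sex-specific table converts each
stage to a self-weighted score and the seven scores sum to the maturity
score S on a 0–100 scale, which a second table maps to dental age.  The
standard maturity tables only reach 16 years, so for a base estimate
strictly above 16 the engine reads the third molar (tooth 38, falling
back to 48) and replaces the estimate with the age that Olze's table
assigns to its stage.  Both ages are kept in the result's provenance.
Replacement rather than averaging is a design choice: the combined
procedure is reported as a single estimate per subject, and the
threshold and behaviour are exposed as parameters (`olze_threshold`).

**London-Atlas-style matching.** The whole dentition (right side by
the atlas convention, left teeth substituting missing right ones) is
compared against age-indexed stage patterns spaced 0.5–1 year apart.
The dissimilarity metric is the mean absolute ordinal stage difference
over shared teeth — the simplest metric that is zero exactly on
agreement and monotone in every tooth.  The chart with minimal mismatch
gives the age; ties are resolved by averaging all tied chart ages,
which generalises the convention of averaging when a dentition lies
between two figures, and makes the result invariant under chart
reordering.  The atlas is sex-agnostic.

### Numerical conventions shared by the engines

* **Lookup tables are knot lists.** An abscissa that hits a knot
  returns the tabulated age exactly (no interpolation arithmetic, so no
  floating-point drift); values strictly between knots are linearly
  interpolated.  Linear interpolation subsumes the conventional rule of
  averaging the two ages at an exact midpoint, and the two routes are
  asserted equal in the tests.
* **Out-of-range sums and scores clamp** to the nearest boundary age
  and set a `clamped` flag instead of erroring.  Cohorts routinely
  extend past a method's table ceiling; clamping is what produces the
  well-known saturation and progressive underestimation of older
  subjects, and the flag keeps it auditable.
* **Contralateral substitution** is allowed in all three engines (the
  classical procedures state it explicitly only for the third molar);
  every substitution is recorded in the result and logged by the CLI,
  so no rule fires silently.
* **Degenerate inputs** (an entirely missing required pair, a stage
  absent from a table, an observation sharing no teeth with any chart)
  raise classed errors; the cohort wrapper converts them into `NA`
  estimates with a note rather than aborting a whole run.

## The evaluation pipeline

For each subject and method the signed error is Δ = estimated − real
age (positive = overestimation) and accuracy is the mean of |Δ|.
Subjects are grouped by age category — the age rounded down to the
whole year — and each category reports its count, mean error, mean
absolute error, and the proportion of subjects estimated correctly
within 1- and 2-year margins.  The margin rule is inclusive
(|Δ| ≤ m) by default, with a switch, since published tables rarely
state which convention they used.  Overall rows are computed over all
subjects and equal the count-weighted mean of the category values
exactly; `weighted_totals()` exposes that arithmetic directly, which is
also how the "Total" rows of published per-age accuracy tables can be
recomputed and checked.

Estimated-versus-real comparisons and between-method comparisons of
absolute error use the classical paired t-test (`stats::t.test`).
Applicability is checked first: zero-variance differences are rejected
as degenerate, and for n < 30 the normality of the differences is
assessed by a Shapiro–Wilk test at α = 0.05, recorded in the result's
note; for n ≥ 30 the check is waived on central-limit grounds.  The
check annotates, it never silently switches tests.

Display rounding (2 decimals, rates in percent) happens only in
`report_tables()`; all aggregation is at full precision.

## The synthetic cohort generator

Real per-subject stage data for such studies are typically not
deposited, so the package carries its own generative model —
`maturation_model()` — used both to simulate cohorts and to derive
reference tables that are exactly consistent with the generating
process.

Each tooth type develops across a fixed age window, with stage-entry
ages equally spaced inside it: windows like first molar ≈ 0.6–9 y,
second molar ≈ 2.7–16 y, third molar 8–21 y are realistic for
permanent teeth, and the late third-molar window is precisely why that
tooth is informative near the 18-year boundary.  One latent maturation
age per subject — chronological age plus a Normal(0, 0.7 y) tempo
shift — drives the Nolla, Demirjian and atlas stages simultaneously,
so the three schemes are correlated within a subject as they are in
real dentitions.  Females lead males by 0.5 years (windows shifted
±0.25 y); the atlas charts are derived at the sex midpoint.  Reader
error is modelled as a symmetric ±1-stage mis-reading with probability
0.05 per tooth, truncated at scheme boundaries, and each tooth is
unobservable with probability 0.03 — plausible single-examiner
conditions, deliberately simple because repeatability statistics are
rarely published.  All draws come from one seeded generator;
`simulate_cohort()` restores the caller's RNG state.

The default cohort composition is the reference study's: 324 subjects
in categories 4–20 with its per-age counts and 168 females, allocated
to categories by largest-remainder apportionment so every (category,
sex) cell is deterministic; within a category ages are uniform on the
one-month grid.

`derive_tables()` evaluates the noise-free median trajectory on an age
grid (default 2–23 y at 0.1-y steps) and aggregates: each distinct
Nolla sum or maturity score becomes a knot whose age is the mean grid
age producing it, third-molar letter stages become Olze entries, and
atlas charts are sampled at 0.5-y spacing.  The Demirjian age table is
tabulated only up to 16.5 y, mirroring the real tables' ceiling, which
is what exercises the Olze trigger: subjects whose maturity score
saturates get a base age slightly above 16 and fall through to the
third molar.  `bias_scenario()` shifts every window earlier by a known
amount, inducing a controlled overestimation against unshifted tables.

### What passing tests do and do not show

With matched tables and zero noise, each engine's cohort MAE is bounded
by its table resolution: sub-stage Nolla values give very fine
resolution (MAE ≈ 0.06 y), while above 16 the Demirjian+Olze pathway
is limited by the ≈1.9-year third-molar stage spacing (mean plateau
error ≈ width/4 ≈ 0.46 y), so its cohort MAE (≈ 0.26 y) sits well
inside the 0.5-y bound without being trivially small.  These round-trip
checks validate the *machinery* — table construction, substitution,
interpolation, clamping, triggering, aggregation — under a model whose
inverse is known.  They deliberately do not validate the historical
tables against real populations: the generator knows nothing of ethnic
heterogeneity, secular trends, inter-examiner disagreement structure,
or the true nonlinear pace of calcification, which is exactly why
published accuracy on real cohorts (reproduced in aggregate via
`load_reference_accuracy()` and `weighted_totals()`) is so much worse
than the synthetic round trip.

### Problem sizes

The shipped tests and the acceptance script run cohorts of 324
subjects (the study composition) for end-to-end properties and smaller
ad-hoc cohorts for unit properties; grids of 0.1 y for table
derivation and 0.5 y for atlas charts.  These sizes were chosen as the
smallest that exercise every rule (Olze triggering needs subjects past
16; the bias power check needs the full n = 324).

## Worked example

```{r example, eval = FALSE}
model <- maturation_model()
tables <- derive_tables(model)
records <- simulate_cohort(cohort_spec(), model, seed = 7)

est <- estimate_cohort(records, tables)
err <- compute_errors(est, records)
report <- report_tables(err, margins = c(1, 2))
report$table1   # per-age mean error / MAE per method
report$table2   # per-age correct-estimation rates (percent)

estimated_vs_real(err[err$method == "NOLLA", ])
compare_methods(err[err$method == "DEMIRJIAN_OLZE", ],
                err[err$method == "NOLLA", ])
```

The same pipeline is scriptable from a shell through the thin wrapper
in `inst/scripts/dentage` (`full-run --seed 7 --out-dir out/`), which
logs every substitution, clamp and Olze trigger as it runs.

## Known limitations

* The engines are faithful to the *procedures*; the historical lookup
  tables themselves are not bundled (several transcriptions circulate,
  which is why every table file must carry a provenance string).  The
  shipped `demo_tables_synthetic.json` is synthetic and says so.
* The maturation model is a test harness, not a demographic model: it
  is not fitted to any population and must not be used to calibrate
  real casework.
* Between-method comparisons use the paired t-test only (with the
  applicability note); no multiple-testing correction is applied, and
  sex is carried descriptively rather than modelled.
* Age categories are the floor of decimal age; subjects at exact
  integer ages stay in their own category.
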