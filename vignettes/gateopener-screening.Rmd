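---
title: "Modelling gateopener FIT pretesting for colorectal cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gateopener FIT pretesting for colorectal cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

## The question the model answers

Screening colonoscopy detects and removes colorectal cancer (CRC) precursor
lesions with high sensitivity, but most screenees have no advanced finding,
adherence to the invasive exam is low, and endoscopy capacity is scarce.
*Gateopener* screening inverts the funnel: everyone is offered a single
quantitative fecal immunochemical test (FIT) once per ten-year screening
interval, evaluated at a hemoglobin threshold far below the manufacturer
preset, and only persons at or above the threshold are invited to
colonoscopy. Lowering the cut-off raises the share of positives (and
false positives), but concentrates colonoscopies on people with elevated
fecal hemoglobin, who carry most of the detectable neoplasms.

`crcscreen` simulates this trade-off. It couples a discrete-time multistate
natural-history engine for the adenoma–carcinoma sequence with a screening
layer (strategies, adherence, drop-out, FIT performance, colonoscopy
effects) and an outcome layer (prevented cases and deaths versus no
screening, resource use, and colonoscopies or FITs per prevented event).

## Natural-history model

Each person occupies one state per annual cycle:

* `no_neoplasm` → `nonadvanced_adenoma` → `advanced_adenoma` →
  `preclinical_crc` → `clinical_crc`, advancing at most one step per year
  with age- and sex-specific annual transition probabilities;
* `clinical_crc` carries two attributes fixed at diagnosis: the detection
  mode (screen-detected or symptom-detected) and the number of completed
  years since diagnosis;
* two absorbing death states, `dead_crc` and `dead_other`.

Within one cycle the event order is fixed: (1) the year's screening events,
(2) disease progression, (3) other-cause death applied to every alive
state, (4) CRC death applied to clinical cases via the case-fatality table
indexed by years since diagnosis and detection mode, (5) the
years-since-diagnosis and age increments. This order is a modelling choice
(screening before progression makes a year-0 offer act on the baseline
states); its alternatives shift results by far less than the parameter
uncertainty the sensitivity analyses explore. There is no half-cycle
correction, and age advances with calendar year.

Screen detection matters through the case-fatality table: screen-detected
cases face lower annual death probabilities than symptom-detected cases
(hazard ratio below one). Years beyond the table are extrapolated flat from
the last row. Colonoscopy moves adenoma carriers back to `no_neoplasm`
(lesion removal), unless the lesion is missed.

## Execution modes

Every arm can run in two modes, which the test suite requires to agree
within Monte-Carlo error:

* **expectation mode** propagates cohort mass deterministically. Because
  enrolment and drop-out are decided per person (not per event), screening
  exposure is correlated across rounds; the cohort is therefore split into
  *participation classes* (never enrolled; enrolled and dropped out after
  round *k*; enrolled throughout), each propagated exactly and summed.
  Diagnostic compliance after a positive FIT is a per-event probability and
  splits mass directly.
* **microsimulation** samples 100,000 (configurable) individuals with a
  seeded RNG; all draws are vectorised per cycle, and a global seed is
  expanded into per-arm substreams keyed by the arm's identity, so adding
  arms to a grid never changes existing arms.

Expectation mode produces the package's headline numbers (it is the
deterministic limit of the microsimulation); microsimulation exists to
verify the engine and to support individual-level extensions.

## FIT performance at low cut-offs

The packaged reference table gives positivity, sensitivity for any
neoplasm, any advanced neoplasm and preclinical cancer, and specificity for
the no-advanced-neoplasm group, for the SENTiFIT-FOB Gold test at cut-offs
17, 10, 8, 6, 4 and 3 µg Hb/g feces, measured in a German
screening-colonoscopy cohort (n = 7398, with 2115 any-neoplasm, 728
advanced-neoplasm and 54 preclinical-cancer participants). Two conventions
matter:

* a test is positive when the hemoglobin value is **at or above** the
  cut-off (closed lower bound — the source does not state the comparison
  operator, so the package fixes one and uses it everywhere);
* **no interpolation** between tabulated cut-offs: the dose–response shape
  between thresholds is unknown, so arbitrary cut-offs are served only by
  re-counting individual records.

The simulator does not consume the aggregates directly. Group sensitivities
are defined over *nested* groups (any advanced neoplasm mixes advanced
adenomas and cancers), while the engine needs one positivity per mutually
exclusive state. `decompose_to_per_state()` peels the nesting from the
inside out: cancers keep their own sensitivity, the advanced-adenoma
positivity is the advanced-neoplasm sensitivity with the cancer
contribution removed, and so on down to the no-neoplasm false-positive
rate. Published aggregates are rounded to one decimal, so the linear solve
can land slightly outside [0, 1]; values are clamped with a warning. The
count-weighted re-aggregation reproduces the source aggregates to well
under half a percentage point at all six cut-offs.

A side effect of this construction is worth noting: the table's
"specificity" denominator (no advanced neoplasm) includes non-advanced
adenoma carriers. The decomposition resolves the ambiguity explicitly
instead of guessing which specificity a downstream simulator should use.

```{r}
decompose_to_per_state(builtin_characteristics(3), blitz_group_counts())
```

## Synthetic data generators

### Quantitative hemoglobin cohorts

To exercise the record-level code without any external data, the package
fits a parametric fecal-hemoglobin model per disease state: a point mass at
zero (no detectable hemoglobin) plus a **two-component log-normal mixture**
(a low-level baseline component and a bleeding component). A single
log-normal cannot follow the observed kink of the positivity curve between
cut-offs 8 and 3 and misses the calibration tolerance; the second component
fixes that. Parameters are fitted per state by minimising the squared
deviation of implied threshold positivities from the decomposed targets
over all six cut-offs (Nelder–Mead from a deterministic grid of starts),
and the calibrated model must reproduce every aggregate characteristic at
every cut-off within 2 percentage points, else calibration errors out.
Generated cohorts apportion the state composition exactly (largest
remainder), draw hemoglobin per state, and floor values below the assay
limit of detection (1.7 µg/g) to zero — all supported cut-offs sit above
it, so classifications are unaffected.

What this emulates: the joint distribution of finding category and
thresholded FIT result of a screening-colonoscopy cohort. What it does not:
demographic covariate structure, within-person correlation of repeated
FITs, or the true shape of the hemoglobin density between and beyond the
calibrated thresholds. Passing tests therefore demonstrate the pipeline's
arithmetic on realistic operating characteristics, not distributional
fidelity to any real cohort.

### Natural-history parameters

The original transition tables of the calibrated German model are not
redistributed with this package, so `generate_natural_history_params()`
draws a complete, schema-valid stand-in: lesion prevalences and transition
rates rising linearly with age, a multiplicative sex effect (men above
women), Gompertz-like background mortality, and case fatality declining
with time since diagnosis, reduced for screen-detected cases by a hazard
ratio of 0.55. The defaults were fixed once at values a German
screening-epidemiology reader would call realistic — e.g. 10-year
cumulative clinical CRC incidence without screening of roughly 1–3% across
the simulated strata, baseline advanced-neoplasm prevalence of ~4–11%
rising with age, a mean preclinical sojourn around 4–5 years — and are not
tuned to reproduce any published outcome. Consequently the package asserts
the *ordering and sign* of strategy comparisons (which are driven by the
screening mechanics and the packaged FIT table), not their exact
magnitudes, which depend on the original parameter tables.

Every generated parameter carries lower/upper 95% CI bounds (relative
half-width 20% by default); `perturb_to_ci_bound()` swaps all prevalence
and transition point estimates for one bound, mirroring the published
parameter-uncertainty sensitivity analysis. Mortality tables are left
untouched by that perturbation.

## Strategies, adherence, drop-out

* `colonoscopy_q10y`: one colonoscopy offer at year 0 (the horizon is one
  10-year screening interval), uptake 15%.
* `biennial_fit`: FIT at cut-off 17 in years 0, 2, 4, 6, 8; first-offer
  uptake 50%; positives proceed to diagnostic colonoscopy with 80%
  compliance.
* `gateopener`: a single FIT at year 0 at any packaged cut-off, uptake 50%,
  same diagnostic compliance.
* `no_screening`: the reference arm; consumes no resources.

Repeat-FIT adherence is sporadic in practice. The package models it as
absorbing drop-out: enrolment is decided at the first offer (refusers never
enter later), and enrolled participants are retained round-to-round with a
constant retention probability solved so that cumulative drop-out across
the five rounds equals the configured 40% — final-round participation is
then 0.50 × 0.60 = 0.30. Under this rule the *mean* per-round
participation is ≈ 0.39, which is deliberately only a loose rendering of
the ≈ 20% biennial participation reported for the German programme: a
first-round uptake of 50% combined with only 40% cumulative drop-out
cannot average 20% per round, so the three published figures are mutually
inconsistent as exact mechanics. The package keeps the stated uptake and
drop-out as exact inputs and treats the 20% as the approximation it is
labelled as. Re-entry after drop-out and re-offers to year-0 colonoscopy
refusers are excluded.

Two further conventions: a colonoscopy triggered by a false-positive FIT
still acts on the true state (it removes incidentally present lesions —
this is precisely why low cut-offs are effective); and positive-FIT
refusers of the diagnostic colonoscopy keep their FIT counted but undergo
no state change. One FIT kit is counted per participation; screening and
diagnostic colonoscopies are pooled in one counter.

Colonoscopy miss probabilities default to 26% (non-advanced adenoma), 9%
(advanced adenoma) and 5% (preclinical cancer), approximating meta-analytic
miss-rate estimates; the preclinical-cancer miss rate is constrained not to
exceed the adenoma rates.

## Outcomes

Prevented cases and deaths are plain differences in 10-year cumulative
counts versus the matched no-screening arm; negative values are kept as-is
(needed to express "prevented fewer" comparisons). Efficiency ratios
(colonoscopies or FITs per prevented case or death) are undefined — `NA`,
not an error — when nothing was prevented, and such cells are excluded from
league tables. Sexes are always simulated separately; pooled summaries sum
counts over both 100,000-person cohorts and recompute ratios. Relative
differences are `100 · (a − b) / b`, rounded to integer percent only in the
league table.

## Numerical choices and degenerate inputs

* Decomposition clamps per-state positivities to [0, 1] with a warning
  (rounded published aggregates); zero subgroup denominators are an error.
* An empty diseased subgroup in record counting yields an undefined (`NA`)
  sensitivity, never zero.
* Case-fatality lookups beyond the table use the last row (flat), with a
  notice.
* Age lookups outside the parameter range clamp to the nearest covered age
  (band lookup, flat at the edges).
* Parameter validation rejects any state whose outgoing probability sum
  (progression plus background mortality) exceeds one, before stepping.
* Unsorted cut-off grids are sorted (decreasing) with a message; duplicated
  cut-offs produce duplicated rows rather than being deduplicated.
* All stochastic outputs take explicit integer seeds; expectation mode is
  fully deterministic.

## Problem sizes

The packaged analyses use cohorts of 100,000 per sex and starting age (50,
60, 70) over a 10-year horizon — the study scale — in expectation mode,
where each arm runs in well under a second. The test suite verifies the
microsimulation against expectation mode with 20 replicates of 100,000
individuals, reproduces the reference FIT table from 10 synthetic cohorts
of 7398 records, and uses smaller toy cohorts (hundreds to tens of
thousands) wherever an exact hand-computable oracle is the point.

## Known limitations

* No pathway stratification (serrated vs. classical), no adenoma
  regression, no cancer-stage stratification, and no distal/proximal split
  (hence no sigmoidoscopy comparator).
* The delay between a positive FIT and the diagnostic colonoscopy is not
  modelled.
* Horizons beyond 10 years would require assumptions about repeated
  gateopener rounds and are out of scope.
* Outcome magnitudes depend on the synthetic parameter stand-in; only
  comparative statements (orderings, signs, approximate relative
  differences) should be read from the defaults.
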