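---
title: "Methods behind gmosr: scoring, norms and simulation for the GMOS-R"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind gmosr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmosr)
```

## The instrument

The General Movement Optimality Score–Revised (GMOS-R) is a detailed,
optimality-based assessment of an infant's general movements (GMs), applied
after the categorical Gestalt classification of the recording as *normal*,
*poor repertoire* (PR), *cramped-synchronized* (CS) or *chaotic*. Every item
credits optimal performance with 2 points, less optimal performance with 1
and non-optimal performance with 0; half points (0.5, 1.5) are allowed on
detail items when a movement falls between two descriptors. The scoresheet
has four regions:

| region            | items | subscore range |
|-------------------|------:|---------------:|
| upper extremities |     8 | 0–16           |
| lower extremities |     8 | 0–16           |
| neck and trunk    |     2 | 0–4            |
| sequence          |     1 | 0–2            |

so the total ranges from 0 to 38 (optimal performance). Two structural rules
are enforced by the scoring engine:

* **Category–sequence coupling.** The sequence item is not scored
  independently. Normal GMs imply sequence 2 (variable), PR implies 1
  (monotonous and/or incomplete), CS and chaotic imply 0 (synchronized or
  disorganized). `score_assessments()` derives the value from the category
  when absent and, in strict mode, rejects records whose provided value
  contradicts it.
* **Ceiling rounding of the total only.** When half points leave the raw sum
  fractional, the final total is rounded *up* to the next whole number.
  Subscores are reported unrounded; rounding is applied once, at the end, so
  that a total is never inflated region by region.

Missing item values make a record unscorable — the instrument has no
partial-score provision, and no imputation is attempted.

The exact item labels of the printed scoresheet exist only in the published
figure; the shipped schema (`inst/extdata/gmosr_schema.json`) therefore
carries a reconstructed item list derived from the instrument's descriptor
vocabulary (amplitude, speed, spatial range, rotations, beginning, end,
smoothness, stiffness), marked as a synthetic transcription in its
provenance note. Item *names* are schema data and can be replaced by a user
file; item *counts*, permitted values and subscore maxima are validated at
load time and are not negotiable. Half points are accepted on the neck/trunk
items under the same rule as all other detail items; the source material
states no separate rule for that region.

## Strata

Recordings are stratified two ways.

**Recording age.** The postmenstrual age (PMA) at recording, in the
obstetric weeks+days notation, falls into six contiguous periods closed on
both printed bounds: extremely preterm (22+0 to 27+6), very preterm (28+0 to
31+6), moderate preterm (32+0 to 33+6), late preterm (34+0 to 36+6), term
(37+0 to 41+6) and post-term (42+0 to 45+6). All arithmetic is day-exact
(`pma_from_birth()` renormalises carries). The age-specific normative table
uses a five-way grouping in which the sparse extremely preterm stratum is
folded into the very preterm block (`norm_age_group()`, label `lt_32`); both
classifications are exposed and neither is privileged.

**Country income group.** Countries resolve to World Bank income groups
(LMIC, UMIC, HIC) through a registry frozen to the snapshot under which the
normative sample was assembled — deliberately not a live feed, so that
percentile lookups remain reproducible against the published tables. The
lookup is case-insensitive and alias-normalised ("USA", "Korea", "Czechia",
"Türkiye", …); unknown countries return an explicit `"unknown"`, never a
silent default.

## Normative percentile ranks

### The unsmoothed percentile definition

GMOS-R totals are ordinal, heavily tied integers, so percentiles are
computed directly on the observed values with no smoothing and no
interpolation: the k-th percentile is the smallest observed value *v* such
that at least k% of the scores are ≤ *v* — the left-continuous inverse of
the empirical distribution function. A consequence embraced by this
definition is that under heavy ties low percentiles can collapse onto the
minimum (`empirical_anchors(c(rep(5, 50), rep(20, 50)))` puts P10 at 5).
Anchors are by construction non-decreasing in k.

### Encoded tables and band lookup

Two reference tables ship as JSON with per-cell provenance notes:

* `full_period`: whole age range, separate LMIC / UMIC / HIC strata, with
  median, quartiles and range (P10/P90 were not published for this table).
* `age_specific`: five recording-age groups, combined LMIC+UMIC versus HIC,
  with full seven-anchor sets for every cell with at least *n* = 15
  recordings. Smaller cells are printed "n.a." in the source and are encoded
  with their *n* and no anchors; querying them raises an error naming the
  cell rather than inventing a band.

The loader validates anchor ordering for every cell and the n ≥ 15 rule for
the age-specific table. One transcription caveat is recorded in the
full-period file's note: the published table prints a median of 33 for
normal GMs in HICs while the accompanying narrative places a score of 35 on
P50 for that stratum; the table is encoded as printed and the discrepancy is
documented, not silently resolved.

`band_lookup()` accepts finalized integer totals only (rounding precedes
interpretation) and returns one of four relations: `below_min`,
`on_anchor`, `between`, `above_max`. When a score equals several anchors
that share a value, all tied names are reported ("on P10 (= min)") instead
of picking one arbitrarily. For `between`, the adjacent anchor *names*
bracket the score ("between P50 and P75").

`build_norm_table()` rebuilds either table shape from a scored cohort,
applying the same percentile definition and suppressing interior anchors for
cells below the threshold while keeping the observed min/max (a rebuilt
cohort, unlike a printed table, always has its extremes available).

## Comparison and agreement statistics

The statistics mirror the large-sample forms conventionally reported for
this instrument; exact small-sample enumeration lives in the test oracles,
not in the API.

* **Mann–Whitney** (`mann_whitney()`): U from midranks,
  Z = (U − n₁n₂/2) / σ with the tie-corrected variance
  σ² = n₁n₂/12 · [(N+1) − Σ(t³−t)/(N(N−1))], two-tailed p from the normal
  law. The sign of Z follows the first group's rank sum. A `correct`
  argument applies the standard 0.5 continuity correction; the plain
  statistic is the default. The corrected variant is the one that tracks
  exact permutation enumeration closely in very small groups (within 0.05
  absolute for 3–7 observations per group in the test suite); the plain
  large-sample p can undershoot the discrete tail noticeably below ~5 per
  group, which is immaterial at normative-cohort sizes.
* **Kruskal–Wallis** (`kruskal_wallis()`): H from midranks divided by the
  tie-correction factor 1 − Σ(t³−t)/(N³−N), p from χ² with k−1 degrees of
  freedom. For two tie-free groups H = Z² exactly.
* **2×2 chi-square** (`chi_square_2x2()`): Pearson N(ad−bc)²/(r₁r₂c₁c₂) on
  1 df, continuity correction available but off by default.
* **Degenerate inputs** return a result object with an `undefined` flag
  (zero tie-corrected variance when all observations are identical), never
  an exception, so batch comparisons over sparse strata do not abort.
* **Interrater agreement**: `icc_pairwise()` is the two-way random-effects,
  absolute-agreement, single-measure coefficient (ICC(A,1)) from the ANOVA
  mean squares of the videos×raters matrix — the form in which rater-level
  shifts count against agreement; `within_delta_agreement()` is the fraction
  of videos with |difference| ≤ δ (default δ = 2 points, the difference
  conventionally regarded as clinically irrelevant); `cohen_kappa()` is the
  usual chance-corrected categorical agreement. `kappa_within_delta()`
  additionally chance-corrects the within-δ rate against a permutation
  chance model; it is labelled non-standard and is not Cohen's kappa.
* **Multiplicity policy** (`flag_significance()`): two-tailed p < 0.05 for
  univariate comparisons; p < 0.017 for families of three pairwise
  comparisons among three groups; other family sizes fall back to
  Bonferroni 0.05/m with a warning. Thresholds are strict inequalities, so
  p = 0.017 in a family of three is not significant.

## The synthetic cohort generator

No patient-level data are distributable, so the package carries a seeded
simulator whose defaults *are* the normative study conditions:

* the joint (age period, income group, GM category) distribution is drawn
  from the encoded cohort-composition counts (n = 1983), which reproduces
  the income mix (7.9 / 17.8 / 74.3%), the period mix (0.8 / 9.3 / 11.8 /
  22.0 / 24.8 / 31.2%) and every per-period category mix by construction;
* totals are drawn per stratum through the piecewise-linear inverse CDF
  joining the published anchors at their cumulative probabilities
  ((0, min), (0.10, P10), (0.25, P25), (0.50, P50), (0.75, P75),
  (0.90, P90), (1, max)), rounded to the nearest integer and clamped to the
  cell's range. Cells without published age-specific anchors fall back to
  the full-period cell for the infant's own income band; cells with only a
  published min–max (chaotic GMs outside HICs) get a uniform draw. The
  fall-back used is recorded per infant in the `anchors_source` ground-truth
  column;
* items are back-filled to match the drawn total exactly: the detail sum is
  distributed over the 18 detail items in random order, each step uniform
  over its feasible values given the remaining sum and capacity (a simple
  feasible construction, not uniform over all compositions). With
  probability 0.25 the raw sum is placed half a point below the total so the
  ceiling rule is exercised;
* metadata follow the cohort description: sex not disclosed with probability
  473/1983 and otherwise female with probability 636/1510; gestational age
  not disclosed with probability 234/1983, otherwise term (uniform 37–41
  weeks) with probability 205/1749 or preterm with a discrete weight vector
  over 22–36 weeks whose quartiles are 26 / 28 / 31 weeks; the gestational
  age is truncated so the recording falls 1–23 weeks after birth (for the
  earliest recordings no feasible gestational age may exist, in which case
  it is left not disclosed);
* reproducibility: each infant uses a substream seeded by
  (root + 1000003·i) mod 2147483629, so the same root seed yields a
  byte-identical cohort and any prefix or subset regenerates independently
  of the run length.

What the simulator does **not** emulate — and what passing round-trip tests
therefore do not establish about real data: item-level correlation
structure (items are back-filled from the total), developmental
trajectories across repeated recordings of one infant, within-stratum
country effects, and any dependence between metadata missingness and the
stratum. It is a testing instrument for the scoring/norms machinery, not a
generative model of infant movement.

## Numerical and design choices

* Printed percentages use round-half-away-from-zero (`round_half_away()`),
  which reproduces the published cohort shares exactly; banker's rounding
  would not.
* Totals use `ceiling()` on sums of half points, which are exactly
  representable in binary floating point, so no tolerance is needed.
* Inverse-CDF draws round half up (`floor(x + 0.5)`) for determinism across
  platforms.
* Band queries reject non-integer scores instead of rounding silently.
* The empirical percentile engine is generic over numeric inputs; the 0–38
  instrument range is enforced where published anchors are constructed, not
  inside the engine.
* Test problem sizes: 10,000 random score vectors against the brute-force
  scoring oracle; 1,000 random multisets of 15–500 scores against the
  percentile scan oracle; 50,000 inverse-CDF draws per published cell for
  anchor recovery within ±1 point; a 20,000-infant cohort for 3σ binomial
  checks of the category mixes. These sizes make the binomial tolerances
  tight enough to be meaningful while keeping the default suite fast.

## Known limitations

* The shipped norms are transcriptions; where the published table and its
  narrative disagree (normal GMs in HICs, above) the package reports the
  table and documents the conflict.
* Published reliability figures (pairwise ICC and kappa ranges) derive from
  the study's own video ratings and cannot be recomputed here; the
  agreement statistics are validated against closed-form and ANOVA oracles
  and against simulated rater pairs instead.
* The original GMOS (range 5–42, tremulous-movement items, hypokinetic
  category) is out of scope, as is any scoring of video material itself:
  inputs are already-assigned item scores and categories.
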