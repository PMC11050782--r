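# gmosr

Scoring, normative percentile ranks and cohort simulation for the **General
Movement Optimality Score–Revised (GMOS-R)** — the detailed 0–38 assessment
of infant general movements (GMs) applied after the categorical Gestalt
classification of a recording as normal, poor repertoire (PR),
cramped-synchronized (CS) or chaotic.

The package is for clinicians and researchers who work with GMOS-R
scoresheets and need to (i) compute totals under the instrument's rules,
(ii) interpret a total against normative percentile ranks stratified by the
infant's country income group (World Bank LMIC / UMIC / HIC) and recording
age, and (iii) run the accompanying nonparametric statistics — without
access to patient-level reference data, which are not distributable.

## The model in brief

Each scoresheet item scores 2 (optimal), 1 (less optimal) or 0
(non-optimal), with half points allowed on detail items. Region subscores
are upper extremities (8 items, 0–16), lower extremities (8 items, 0–16),
neck and trunk (2 items, 0–4) and sequence (1 item, 0–2); the total is their
sum, rounded **up** to a whole number when half points leave it fractional:

total = ⌈ Σᵣ Σᵢ xᵣᵢ ⌉ ∈ {0, …, 38}

The sequence item is coupled to the GM category (normal → 2, PR → 1,
CS/chaotic → 0). Percentile ranks are computed without smoothing: Pₖ is the
smallest observed score *v* with F̂(v) ≥ k/100, so under heavy ties low
percentiles can coincide with the minimum. Group comparisons use the
Mann–Whitney Z and Kruskal–Wallis H with automatic tie correction;
interrater agreement uses the pairwise ICC(A,1), Cohen's kappa and the
fraction of rater pairs within 2 points. A seeded simulator generates
synthetic cohorts with the normative sample's joint (age period × income
group × GM category) structure and per-stratum score distributions, so every
component is testable without patient data.

## Worked example

Score one PR recording and place the total in the norms:

```r
library(gmosr)
schema <- gmosr_schema()
vals <- c(1.5, 1, 1, 0.5, 1, 1.5, 1, 0.5,   # upper extremities
          1, 1, 0.5, 1, 1.5, 1, 0.5, 1,     # lower extremities
          1.5, 1.5)                          # neck, trunk
rec <- c(list(category = "poor_repertoire"),
         setNames(as.list(vals),
                  setdiff(schema$columns, schema$sequence_column)))
compute_score(rec)
#> GMOS-R score
#>   UPPER_EXTREMITIES  8
#>   LOWER_EXTREMITIES  7.5
#>   NECK_AND_TRUNK     3
#>   SEQUENCE           1
#>   raw sum 19.5 -> total 20
```

The sequence score (1) was derived from the category; the half-point raw sum
19.5 was rounded up, once, at the end. Interpreting the total of 20:

```r
band_lookup(20, "poor_repertoire", "HIC")
#> GMOS-R 20 (poor_repertoire, HIC, ALL): between P25 and P50

band_lookup(20, "poor_repertoire",
            classify_income_group("India"),          # "LMIC"
            period = classify_age_period(38, 2))     # "term"
#> GMOS-R 20 (poor_repertoire, LMIC_UMIC, term): between P50 and P75
```

The same total sits between P25 and P50 against the high-income full-period
norms, but between P50 and P75 for a term-age recording judged against the
combined LMIC+UMIC age-specific norms — the socioeconomic stratification the
normative tables exist to express. Simulation, summary reports, group
comparisons and agreement statistics are available as functions
(`simulate_cohort()`, `summarize_cohort()`, `mann_whitney()`,
`icc_pairwise()`, …) and through the bundled command-line tool
(`inst/cli/gmosr`, subcommands `score`, `percentile`, `summarize`,
`compare`, `agreement`, `simulate`, `build-norms`).

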