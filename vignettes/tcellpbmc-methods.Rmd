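---
title: "Methods: statistical analysis of T cell:PBMC immunogenicity assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical analysis of T cell:PBMC immunogenicity assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcellpbmc)
```

## The assay and its data model

A T cell:PBMC immunogenicity assay challenges purified CD4⁺ T cells,
co-cultured with irradiated autologous PBMCs, with a panel of compounds
and reads out activation in three ways: ³H-thymidine incorporation at
day 6 and at day 8 (cpm; sextuplicate wells, 1×10⁵ CD4⁺ T cells per
well) and IL-2 ELISpot (spots per well; triplicate wells, 5×10⁵ cells
per well). The package's atomic record is one measured well:
`(donor_id, compound, readout, replicate, value, cells_per_well)`.
Untreated wells are ordinary rows with the reserved compound token
`BASELINE`, so a single CSV carries a full cohort; every treated
`(donor, readout)` must have matching baseline rows.

The 6/6/3 replicate design is a default, not a hard constraint:
`validate_cohort()` reports deviations (replicate counts, missing
baselines, inconsistent cell numbers) and only escalates to an error
under `strict = TRUE`. ELISpot values are stored as reals — scanner
software sometimes exports averaged counts — and are validated as
integers only in strict mode.

## Responder classification

For each (donor, compound, readout) the **stimulation index** is the
ratio of the treated to the baseline replicate mean. The ratio of means
(rather than a mean of per-well ratios) is the standard SI convention
and stays well defined when replicate counts differ. The **statistical
criterion** is the classical equal-variance two-tailed unpaired Student
t-test (df = n₁+n₂−2) of treated vs baseline raw values. A readout is
**positive** when SI > 2 and p < 0.05, both strict: SI = 2 exactly or
p = 0.05 exactly is negative. A **donor responds** to a compound when at
least one available readout is positive; missing readouts are tolerated
so partial cohorts can still be analysed. No multiple-testing correction
is applied across compounds or readouts — the procedure is a fixed
per-pair decision rule, and the SI > 2 requirement already makes it
conservative relative to α alone (on signal-free simulated cohorts the
empirical per-readout positivity rate is below 0.5%, versus the nominal
5%; the test suite checks the ≤ α bound over ≥ 2,000 simulated triples).

Degenerate inputs follow the t-statistic's limits: zero pooled variance
with equal means gives p = 1, with unequal means p = 0 (flagged). A
non-positive baseline mean is an error unless a floor is configured
(`baseline_floor`), in which case the SI is computed against the floor
and flagged.

Day-6 and day-8 proliferation are treated as two independent readouts,
each compared against its own day-matched baseline wells; cpm drifts
over two extra days of culture, so pooling baselines across days would
bias both the SI and the well scoring. ELISpot baseline wells are
treated identically to treated wells (co-stimulation is added to all
conditions in this format, so it cancels in the comparison).

## Precursor-frequency estimation

Because each proliferation well receives a known number of CD4⁺ T
cells, the fraction of wells without a proliferative response carries
frequency information under the single-hit Poisson model: a well is
negative when it received zero antigen-specific precursors, which
happens with probability exp(−f·N) at per-cell frequency f and dose N.
Wells are scored positive when cpm strictly exceeds 2 × the day-matched
baseline mean; negative/total counts are pooled over day 6 and day 8
(12 wells under the full design) and the frequency is the closed form

F = −ln(n_negative / n_total) / N,

which is exactly the maximum-likelihood estimator of the single-dose
single-hit binomial model. When *every* well responds, the negative
count is replaced by 0.1, capping the estimate at ln(10·n_total)/N —
40.94 per 10⁶ at 6 wells of 10⁵ cells, 47.87 at 12. The substitution
applies only at zero negatives; no continuity correction is used
elsewhere. A donor with no scored-positive wells estimates exactly 0.
Frequencies are estimated from proliferation wells only: ELISpot wells
are bulk-cultured and re-plated in this format, so well-level
limiting-dilution logic does not apply to them. Cohort summaries report
the arithmetic mean and SEM of the per-donor estimates per 10⁶ cells
(SEM is reported as 0 and flagged at n = 1). No confidence intervals
are attached to the per-donor closed form; the estimator is a point
summary of 12 wells.

### The likelihood oracle and its numerics

`frequency_mle_oracle()` validates the closed form independently: a
coarse log-spaced grid brackets the maximiser of the binomial
log-likelihood, and golden-section search refines it. One numerical
subtlety matters: near the optimum the log-likelihood is flat, and
*values* at candidate points agree to ~1e−16 while their difference is
quadratically small, so a value-comparison search stalls at the square
root of machine epsilon (~1e−8 relative). The oracle therefore compares
candidates through a stable expression for the likelihood *difference*
(subtraction of nearby doubles is exact; `expm1`/`log1p` carry the
rest at full relative precision), which lets the bracket shrink to
1e−12 relative. The suite checks agreement with the closed form to
within 1e−9 relative error for every (n_negative, n_total) with
1 ≤ n_negative < n_total ≤ 24 at three cell doses.

### Estimator behaviour

Two biases are inherent to the design and are demonstrated, not hidden,
by the validation harness (1,000 simulated cohorts of 26 donors, 12
wells × 10⁵ cells, noise-free scoring):

- at a moderate planted frequency (5×10⁻⁶ per cell) the grand mean
  recovers the truth within 15%, with a small upward Jensen bias from
  the convexity of −ln;
- near saturation (5×10⁻⁵ per cell, where exp(−f·N) ≈ 0.007) most
  donors have zero negative wells, the 0.1 substitution pins their
  estimate at the 47.87-per-10⁶ cap, and the grand mean is biased
  *toward the cap* (below the truth here); the harness checks the
  simulated mean against the exact binomial expectation of the
  estimator. Frequencies at or above the cap are reported as "at least
  the cap" in any scientific reading.

## The synthetic cohort generator

The generator exists because donor-level raw data for this assay class
are rarely published; it provides a ground-truthed stand-in with the
same design (26 donors × 6 compounds, 6/6/3 replicates, 10⁵/10⁵/5×10⁵
cells per well). Its layers:

1. **Planted truth.** Each compound gets `n_responders` donors with a
   per-cell precursor frequency drawn uniformly from a configured range;
   all other donors get frequency 0.
2. **Precursor seeding.** Each well receives Poisson(f·N) precursors —
   the same single-hit assumption the estimator inverts.
3. **Proliferation noise.** cpm = B + k·S with B lognormal (median 500
   cpm, geometric SD 1.3 — typical of unstimulated ³H-thymidine wells)
   and S an independent lognormal per-precursor increment (median
   2,000 cpm, same geometric SD). With one precursor the expected SI is
   (500+2000)/500 = 5.
4. **ELISpot noise.** Poisson counts with mean 5 (background) + 2 per
   precursor.

All noise parameters are config-exposed; none is an estimate of any
particular instrument's behaviour — published reports of this assay
give no baseline cpm or spot magnitudes, so these are stand-ins chosen
as the simplest models with the right support and overdispersion.
Precursor expansion over the 6–8 day culture is folded into the
per-precursor increments rather than modelled dynamically (the analysis
never observes the dynamics), and co-stimulation/re-stimulation effects
are absorbed into the ELISpot signal parameters. No immunological
mechanism is modelled: no epitope/HLA-binding structure, and no
drug-specific suppression (TNF-α blockers, for instance, are suspected
of suppressing proliferation in the real assay — a confounder this
generator cannot exhibit).

### Presets

- `"reference"` — the calibrated cohort: planted responder counts
  KLH 26, CMV 26, infliximab 1, adalimumab 2, rituximab 5,
  natalizumab 7 of 26 donors, matching the published cohort's in vitro
  responder table; responder frequencies 3–6×10⁻⁵ per cell for the
  antibodies and 4–8×10⁻⁴ for the controls, deliberately far above the
  decision boundary so the planted sets are recovered exactly through
  the default noise; responders are the first k donor ids per compound
  (stable across seeds); fixed generator seed 42. This preset is a
  *named dataset*: the seed is part of its definition.
- `"null"` — the same design with no signal anywhere, for
  false-positive calibration.
- `"hard"` — responder frequencies straddling the decision boundary
  (2×10⁻⁶–2×10⁻⁵), for power studies; recovery is not guaranteed.

What passing tests on these cohorts shows — and what it does not: the
pipeline recovers planted truth under the generator's assumptions
(independent wells, lognormal/Poisson noise, no plate or day effects,
no drug interference with the readout). Real cohorts can violate every
one of those; agreement on synthetic data validates the *software and
the statistics*, not the assay's biological calibration. One behaviour
worth knowing: with a triplicate ELISpot readout over a Poisson(5)
background, chance false positives at roughly the 1% per-triple level
are expected and observed across generator seeds; at the reference
preset's own seed the recovered responder sets are exact, and across
seeds planted responders are never missed (the test suite checks both).

## HLA representativeness

`hla_allele_frequencies()` tabulates chromosome counts per locus from a
typing-report-layout genotype table. Two conventions handle a donor
with a single reported allele: `HOMOZYGOUS` (default) counts it twice —
the standard reading of a typing report — and `SINGLE` counts it once,
treating the blank as a typing failure; whether a lone allele means
homozygosity genuinely cannot be determined from a report alone, so
both are exposed and the choice is recorded in the output attributes.
Allele (chromosome) frequency, not donor carrier frequency, is the
default because it is the quantity reference population tables publish.
`population_correlation()` pairs cohort and reference frequencies over
the union of alleles (absent entries 0, any `OTHER` remainder bucket
dropped — it is not an allele) and computes Pearson's r with its
two-tailed p-value via `stats::cor.test`; with fewer than 3 alleles or
a zero-variance vector the comparison is refused or flagged rather than
computed. The package ships a 26-donor cohort genotype table and a
clearly-labelled **synthetic** reference frequency table for examples
and tests; the synthetic table is not a real population distribution
and must be replaced for any scientific comparison.

## Design choices on genuinely open points

- **Mean SI of responders** (the risk-plot ordinate) averages over the
  responders' *positive* readouts only, since the plot describes the
  responders' response levels; averaging all their readouts would mix
  in negative readouts of multi-readout donors. The plot table exposes
  the inputs needed to compute the alternative.
- **Day-6 vs day-8 wells** are modelled as independent well sets (the
  physical protocol may re-use plates; nothing in the analysis depends
  on it).
- **Reported precision.** Responder percentages and per-10⁶
  frequencies are reported to one decimal in summaries; full precision
  is kept internally and in all intermediate objects.

## Problem sizes used in validation

The test suite simulates: the full 26-donor reference cohort (2,730
wells) for end-to-end recovery; five 26-donor null cohorts (2,340
donor-compound-readout triples) for the false-positive bound; 1,000
cohorts of 26 donors × 12 wells for parameter recovery plus 200 at the
saturating frequency; and the complete MLE-equivalence grid (276
(n_negative, n_total) pairs × 3 cell doses). These sizes give
Monte-Carlo error comfortably inside every asserted tolerance while the
whole suite runs in well under a minute.

## Known limitations

- The per-donor frequency estimator is censored above at the
  substitution cap; cohorts containing saturating responders (both
  control antigens in the reference preset) have downward-biased means
  relative to the (unobservable) truth.
- The generator's noise model is deliberately minimal: no plate/edge
  effects, no between-day correlation, no donor-level baseline
  heterogeneity beyond the lognormal draw, no drug interference with
  proliferation or spot formation.
- The Student t-test is applied to raw cpm, which is right-skewed;
  this mirrors the assay's standard analysis rather than a
  statistically optimal choice (no log transform, no Welch correction,
  no nonparametric alternative is offered).
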