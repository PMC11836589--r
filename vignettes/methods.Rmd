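---
title: "Methods: rest-activity rhythm, sleep and HRV analysis in actirhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rest-activity rhythm, sleep and HRV analysis in actirhythm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actirhythm)
```

## Scope and data model

`actirhythm` analyses two physiological signals from case-control cardiac
cohorts: minute-epoch wrist actigraphy counts and RR-interval series, plus a
per-subject metadata/outcome table. Epoch timestamps mark the *start* of each
epoch and every interval in the package is half-open `[start, end)`, so
binning is unambiguous. All timestamps are handled in UTC; clock time is the
time-of-day component of the timestamp.

## Nonparametric circadian indicators

Disturbed rest-activity rhythms in acutely ill patients are poorly captured
by fitting a 24-h sinusoid, so the package deliberately avoids cosinor
fitting and uses the nonparametric indicator family computed from hourly
averaged activity. The defining formulas are stated in the help pages of
`interdaily_stability()`, `intradaily_variability()`, `m10_l5()`,
`relative_amplitude()` and `dichotomy_index()`. Points where a genuine
convention had to be chosen:

* **Hourly resolution.** Indicators are computed from hourly means of minute
  epochs; hours with more than half of their epochs missing are dropped, not
  imputed, so that missingness cannot fabricate rhythm. Consecutive-hour
  pairs spanning a dropped hour are skipped in IV with the normalization
  unchanged.
* **M10/L5 per day, then averaged.** The most/least active windows are
  searched per complete 24-h block with circular wrap and the per-day values
  averaged; a search on the across-day mean profile is available via
  `average_profile = TRUE`. Window ties break to the earliest start hour so
  results are deterministic.
* **Circular averaging of midpoints.** Clock times of M10/L5 are averaged as
  angles. Near-midnight midpoints otherwise average to noon; the large
  between-subject spread of L5 timing in ICU patients makes this a real,
  not theoretical, hazard.
* **Per-day relative amplitude.** RA is computed per day and averaged, so it
  can differ from `(M10 − L5)/(M10 + L5)` evaluated on the averaged extremes
  by a small Jensen-type gap (about 10⁻² on realistic signals).
* **Dichotomy index on epochs with a strict inequality.** In-bed epochs equal
  to the out-of-bed median do not count. The in-bed set comes from bed-time
  annotations when available, otherwise from the detected major rest period.
* **Day/night windows.** Day `[06:00, 22:00)` and night `[22:00, 06:00)` are
  the main free parameters of the day/night activity statistics; both are
  configurable. Activity SDs are sample SDs across epochs by default; an
  across-day-means variant (`per_day_means = TRUE`) and a population-SD flag
  exist because reporting conventions differ and the epoch-versus-day choice
  is genuinely underdetermined in the literature.
* **Eligibility.** Recordings shorter than 3 days (non-missing time) are
  excluded from circadian analysis; the boundary is inclusive, so exactly
  3.0 days passes. Sleep parameters are still computed for short recordings.

## Sleep scoring and parameters

Sleep/wake is scored from the observation that there is less motion during
sleep than during wakefulness: a 7-epoch weighted moving average (lags −4…+2,
Cole-Kripke-style weights normalized to sum to 1) is compared with a
threshold in counts/min (default 40). The threshold is scale-dependent —
device counts are not standardized across manufacturers — and reproducing any
proprietary device algorithm numerically is a non-goal; the scorer is a
transparent, configurable replacement.

The major rest period per day is the longest sleep-dominated span (sleep
fraction ≥ 0.7 after bridging wake gaps ≤ 60 min, minimum 3 h), assigned to
the day of its midpoint. Annotated bed intervals always override detection.
Within a rest interval, sleep onset is the first run of ≥ 10 consecutive
sleep minutes; SOL, TST, WASO and awakenings follow from that span, and
SE = TST / rest duration × 100. These conventions make
`SOL + TST + WASO = rest duration` an exact identity, which the tests
enforce. TST is counted strictly within the major rest interval, so daytime
napping is not included — a definitional divergence from device reports that
sum naps.

## HRV metrics

RR cleaning masks intervals outside `[300, 2000]` ms or differing from the
previous valid interval by more than 20%; successive-difference metrics use
only adjacent valid pairs, which makes them invariant to invalid padding.
Sample (n−1) variances are used throughout. Poincaré dispersion is computed
by the successive-difference algebra — `SD1 = √(Var(ΔRR)/2)`,
`SD2 = √(2·SDRR² − Var(ΔRR)/2)` — rather than ellipse fitting, so
`SDRR² = (SD1² + SD2²)/2` holds identically. Under the sample convention
`SD1 = RMSSD/√2` holds only up to a factor `√(m/(m−1))` in the number of
pairs m; the tests check it at the corresponding tolerance. pNN50/pNN20 use a
strict `>`, so a difference of exactly 50 ms does not count — conventions
differ on this point and the choice is documented rather than silent.

Deceleration capacity uses phase-rectified signal averaging with the standard
anchor rule (an interval longer than its predecessor, excluding increases
above 5% as likely artefacts), segments of half-length L = 2, and
`DC = (X(0) + X(1) − X(−1) − X(−2))/4`. A monotone non-increasing series has
no anchors and DC is reported as undefined (an error, or `NA` from the
indicator wrapper), never as 0. Note that with the 5% filter an alternating
±6% series has no anchors at all; the filter is configurable for sensitivity
analyses.

Patient recordings (24 h) and control recordings (15 min) are analysed over
the full cleaned record without duration normalization, mirroring common
study practice; the cleaned duration is reported alongside the metrics for
transparency.

## Statistics

Group comparisons use two-sided pooled-variance t tests (Welch optional) and
ANCOVA (`outcome ~ group + covariates`, reported effect = adjusted group
coefficient, p from its t statistic), with age, gender (coded 0/1 through the
model matrix) and BMI as the standard adjustment set. Prognosis associations
use Pearson correlation (binary outcomes on 0/1 coding, i.e. point-biserial)
and partial correlation of residuals with `df = n − 2 − k`. With no
covariates, ANCOVA reduces exactly to the pooled t test and partial
correlation to Pearson — both reductions are tested to 10⁻⁹. No
multiple-testing correction is applied by default, matching the two-star
(.05/.01) reporting convention of the field; a Benjamini-Hochberg column is
available behind `p_adjust = TRUE`. Missing cells (e.g. mean readmission days
for patients never readmitted) are dropped pairwise per test. Categorical
baseline rows (gender) use a chi-square test, since a t test on category
labels is not meaningful.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be validated by
parameter recovery. Expected activity at clock time t is
`max(0, mesor + amplitude·cos(2π(t − acrophase)/24) + noise)`, with separate
day/night noise SDs, and with probability `fragmentation_p` an epoch instead
draws from the opposite period (the antiphase clock time with the other
period's noise SD). Counts are clipped at zero then rounded, as devices
report integer counts. RR series are a subject mean plus white noise (SD
`short_term_sd_ms`, so RMSSD ≈ `short_term_sd_ms·√2`) plus a slow AR(1)
drift (coefficient 0.995/beat, stationary SD `long_term_sd_ms`), which gives
closed-form ground truth for RMSSD, SDRR, SD1, SD2 and their ratio.

The group templates encode the qualitative case-control phenotype: patients
get a lower mesor and amplitude, a delayed acrophase (15.5 vs 13.5 h), triple
the fragmentation (0.15 vs 0.05), shorter monitoring (about 6 vs 14 days, the
patient span jittered with SD 2 days so that some recordings fall under the
3-day exclusion, as happens in practice), and reduced short-term RR
variability (13 vs 22 ms) on 24-h versus 15-min recordings. Amplitude is set
*above* the mesor in both templates so that the clipped cosine is genuinely
quiescent across the bed window — with amplitude below the mesor the
"night" of a pure cosine is too active for a sleeping human, and the control
bed window is aligned with the quiescent span `[22:00, 06:00)` for the same
reason. Demographics (age, gender mix, BMI) are drawn per group from the
distributions typical of such cohorts. Between-subject jitter is log-normal
on scales, wrapped-normal on the acrophase and logit-normal on
fragmentation, all configurable via `jitter_spec()`.

Outcomes are generated from *ground-truth* (noise-free) indicator values via
`outcome_model()`: a linear predictor over z-scored indicators plus Gaussian
noise, identity link for continuous/count outcomes and a latent-Gaussian
threshold at a configurable prevalence for binary ones (keeping
point-biserial correlations analyzable). Ground truth lives in a sidecar
table that the analysis stages never see, so recovery tests cannot leak.
`simulate_null_cohort()` provides an indicator-level null (all columns
independent of group and of each other) for fast type-I calibration.

What the generator does **not** emulate: daytime napping, weekend/weekday
structure, device wear-time gaps, non-Gaussian count distributions, and
physiological HRV spectra (LF/HF bands) — so passing recovery tests shows the
estimators are correct for the stated model, not that real ICU data are this
clean. In particular, real patients show far lower IS and higher IV than the
smooth synthetic rhythm; the synthetic cohort reproduces the *directions* of
the case-control contrasts, not published group means.

## Validation strategy and problem sizes

The test suite validates the pipeline at four levels, with the problem sizes
chosen to keep the full suite in the minutes range: (1) closed-form limits
(IS = 1 on identical days, IV = 4 on hourly alternation and ≈ 2 on white
noise over 50 seeds, RA = 1 at a silent trough, dichotomy = 100% for
uniformly quiescent in-bed epochs); (2) equivalence with naive brute-force
reference implementations on 100 random inputs each for IS, IV, the M10/L5
window search and Poincaré dispersion, at 10⁻⁹; (3) algebraic identities on
arbitrary random inputs; and (4) parameter recovery — acrophase within 0.5 h
noise-free and 1 h on 50 noisy jittered subjects, RA strictly monotone in
amplitude, IV/fragmentation Spearman ρ > 0.9 over 10 levels × 30 seeds,
direction of all thirteen case-control contrasts under ANCOVA in ≥ 90% of
100 simulated studies of 30 + 17 subjects, and empirical type-I error of all
four tests within the 95% binomial band of α = 0.05 over 500 null
replicates. `scripts/acceptance.R` re-runs the same computations from
scratch (25 seeds for the directional block) and writes the numbers to JSON.

## Known limitations

* The sleep threshold (counts/min) must be tuned to the device's count
  scale; there is no universal default.
* IS/IV values depend on the hourly-averaging convention; comparisons with
  studies computing them at other resolutions are not exact.
* DC depends on the anchor filter and segment length; published values vary
  with both.
* The day/night window choice moves the day/night activity statistics; it is
  surfaced as an explicit parameter rather than hidden.
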