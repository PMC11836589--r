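# actirhythm

Rest-activity rhythm, actigraphic sleep, and heart rate variability (HRV)
analysis for case-control cardiac cohorts.

Patients hospitalized with an acute myocardial infarction (MI) show disturbed
sleep and a flattened, delayed circadian rest-activity rhythm, and both have
been linked to prognosis. `actirhythm` implements the analysis pipeline such a
study needs, end to end:

- **Actigraphy handling** — read minute-epoch wrist-actigraphy count series
  (`timestamp,counts[,in_bed]` CSV), validate and gap-fill them, average into
  hourly profiles, and apply the recording-length exclusion rule (at least 3
  days for circadian analysis).
- **Nonparametric circadian indicators** — because disturbed rhythms are not
  well modeled by a 24-hour sinusoid, the pipeline uses the nonparametric
  indicator set computed from hourly averaged activity:
  - interdaily stability `IS = N Σₕ(x̄ₕ − x̄)² / (24 Σᵢ(xᵢ − x̄)²)`,
  - intradaily variability `IV = N Σ(xᵢ − xᵢ₋₁)² / ((N−1) Σ(xᵢ − x̄)²)`,
  - M10 / L5 (mean activity of the most active 10 and least active 5
    consecutive hours, with circular window search per day) and their
    midpoints (circularly averaged clock times),
  - relative amplitude `RA = (M10 − L5)/(M10 + L5)`,
  - the actigraphic dichotomy index I<O (percentage of in-bed epochs with
    activity strictly below the median out-of-bed activity),
  - day/night activity means and SDs.
- **Sleep analysis** — Cole-Kripke-style weighted-window sleep/wake scoring,
  major rest period detection, and the parametric sleep set: sleep onset
  latency (SOL), total sleep time (TST), sleep efficiency (SE), wake after
  sleep onset (WASO), and number of awakenings.
- **HRV analysis** — RR-interval cleaning, time-domain metrics (mean RR, HR,
  SDRR, RMSSD, pNN50, pNN20), Poincaré dispersion (SD1, SD2, SD1/SD2), and
  the deceleration capacity of heart rate (DC) by phase-rectified signal
  averaging.
- **Statistics and reporting** — independent t tests, ANCOVA controlling for
  age, gender and BMI, Pearson and partial correlation of indicators with
  prognosis outcomes, assembled into the six standard report tables
  (baseline, sleep, circadian, HRV, and two prognosis-correlation matrices).
- **Synthetic cohorts** — a generator of activity series (clipped 24-h cosine
  with period-specific noise and fragmentation swaps), RR series (white
  short-term variability plus slow AR(1) drift), metadata and outcomes with
  known ground-truth parameters, so that every stage is testable by parameter
  recovery without patient data.

## Worked example

```r
library(actirhythm)

# simulate one week of a healthy subject's wrist activity
act <- simulate_activity(control_template()$rhythm, seed = 1)
circadian_indicators(act)
#> # A tibble: 1 × 12
#>      is     iv   m10 midpoint_m10_h    l5 midpoint_l5_h    ra dichotomy_index
#>   <dbl>  <dbl> <dbl>          <dbl> <dbl>         <dbl> <dbl>           <dbl>
#> 1 0.993 0.0937  188.           13.5  10.7          1.86 0.892            95.7
#> # ℹ 4 more variables: day_mean <dbl>, day_sd <dbl>, night_mean <dbl>,
#> #   night_sd <dbl>
```

IS near 1 says the day-to-day pattern is highly repeatable; IV near 0.09 says
hourly activity changes smoothly; the most active 10 hours average 188
counts/min centred at 13:30, the least active 5 hours 11 counts/min centred
at 01:52, giving a strong day-night contrast (RA 0.89); 96% of in-bed epochs
fall below the median out-of-bed activity.

A full case-control study runs off a file manifest:

```r
sim <- simulate_cohort(n_mi = 34, n_ctrl = 17, seed = 1)
manifest <- write_cohort(sim, "cohort_dir")
res <- analyze_cohort(manifest, out_dir = "results_dir")
res$tables$table3   # circadian indicators, ANCOVA-adjusted for age/gender/BMI
```

or from the shell via the bundled CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","actirhythm.R",package="actirhythm"))')" \
  analyze --cohort-manifest cohort_dir/manifest.json --out results_dir
```

which writes `table1.csv` … `table6.csv` plus a deterministic `run_log.json`.

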