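# coolsleep

Statistical analysis of mattress-cooling crossover studies of sleep.

In a two-night crossover design, each subject sleeps once on a
high-heat-capacity cooling mattress (HM) and once on a regular mattress
(LM), with polysomnography, core body temperature (CBT), proximal back skin
temperature (PBT), mattress surface temperature (MAT) and heart rate (HR)
recorded over 450 min after lights-off. `coolsleep` is for sleep and
thermophysiology researchers who want to test whether conductive body
cooling increases slow-wave sleep (N3), whether the effect travels through
the core-to-skin heat flow indexed by the CBT−PBT gradient, and where in the
~110-min NREM-REM cycle the effect lands.

The package provides, end to end:

* a **synthetic cohort generator** (three study subpopulations, n = 15/33/24
  by default) producing paired hypnograms and physiological series with the
  published effect structure, since the original raw recordings are not
  public;
* **aggregation** to the 45 × 10-min analysis grid, nocturnal summaries and
  per-subject HM−LM deltas Δ, with the night split at 190 min;
* **per-bin paired t tests** with Benjamini–Hochberg FDR control (family =
  the 45 bins of one variable), **cumulative-sum** timecourse analysis,
  repeated-measures condition tests (for two levels, F = t² exactly), and
  effect sizes (Cohen's d = mean(Δ)/SD(Δ), η², r²);
* **cycle analysis**: detrended periodogram over bins 1–44 (peak at
  k/440 min⁻¹), folding into four 110-min cycles, per-subject and
  population-mean **cosinor** fits `y = M + A·cos(2π(t − φ)/110)` with the
  Hotelling-type zero-amplitude rhythmicity test and wrapped acrophase
  differences;
* single-mediator **mediation** ΔCBT → ΔPBT → {ΔN3, ΔREM, ΔHR} with
  percentile bootstrap CIs (1000 resamples);
* **median-split heterogeneity** analysis by ΔCBT-PBT with the G² study
  balance test.

## Worked example

```r
library(coolsleep)

spec   <- cohort_spec(seed = 7)          # defaults encode the study world
cohort <- generate_cohort(spec)          # 72 subjects x 2 nights
deltas <- delta_cohort(bin_cohort(cohort))

n3 <- vapply(deltas, function(d) d$nightly[["n3"]], 0) * 45
sprintf("Nightly N3 gain: %.1f +/- %.1f min/7.5 h (d = %.3f)",
        mean(n3), sd(n3), cohens_d_paired(n3))

m <- delta_matrix(deltas, "n3"); m[is.na(m)] <- 0
gs <- group_spectrum(lapply(seq_len(ncol(m)), function(i) m[-1, i]))
grad <- vapply(deltas, function(d) d$nightly[["gradient"]], 0)
n3p2 <- vapply(deltas, function(d) d$part2[["n3"]], 0)
ct   <- pearson(grad, n3p2)
cn3  <- population_cosinor(fold_cohort(deltas, "n3"))
cre  <- population_cosinor(fold_cohort(deltas, "rem"))
med  <- mediate(vapply(deltas, function(d) d$part2[["cbt"]], 0),
                vapply(deltas, function(d) d$part2[["pbt"]], 0),
                n3p2, n_boot = 1000, seed = 7)
```

Output (seed 7):

```
Nightly N3 gain: 9.4 +/- 24.8 min/7.5 h (d = 0.379)
Cycle peak: 0.0091 /min (period 110 min)
Gradient vs N3 (2nd part): r = 0.551, p = 0.0000
Delta-N3 acrophase 10.7 min, delta-REM 51.6 min
Mediation: ACME -0.943 (p = 0.000), direct 0.234 (p = 0.438)
```

Reading the numbers: the cooling night adds ~9 min of N3 per 7.5 h (small
effect, d ≈ 0.38); the NREM-REM cycle period recovered from the data is
110 min (frequency 0.0091 min⁻¹); subjects with a larger increase in the
CBT−PBT gradient gain more N3 in the second night part (r = 0.55); the N3
effect peaks near the start of the sleep cycle and the REM effect mid-cycle
(~41 min apart here); and the core-temperature effect on N3 runs through the
skin mediator (significant negative indirect effect — a larger core drop,
via a larger skin drop, yields more N3 — with no direct path).

A full run — nocturnal summary table, correlation matrix by night part,
per-bin and cumulative-sum tests, spectra, folded cycles, cosinor, mediation
and median-split outputs as CSV/JSON — is one call:

```r
run_pipeline(default_config(seed = 1, out_dir = "out"))
```

or from the shell:

```sh
Rscript -e 'coolsleep::coolsleep_cli()' all --seed 1 --out out
Rscript -e 'coolsleep::coolsleep_cli()' simulate --seed 1 --out cohort_csv
```

## Data formats

Hypnogram CSV: `subject_id,study,condition,epoch_index,stage` (900 30-s
epochs per night, stages W/N1/N2/N3/REM, conditions HM/LM). Physio CSV:
`subject_id,study,condition,variable,sensor_id,time_s,value` with time in
seconds since lights-off in `[0, 27000)`. `write_cohort()` /
`read_hypnogram_csv()` / `read_physio_csv()` round-trip these; see
`vignettes/coolsleep-methods.Rmd` for the model, calibration and design
decisions.
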