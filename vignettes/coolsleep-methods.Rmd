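---
title: "Methods: models, calibration and design choices in coolsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in coolsleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

coolsleep analyses two-night crossover studies in which each subject sleeps
once on a high-heat-capacity cooling mattress (HM) and once on a regular
mattress (LM), with polysomnography, core body temperature (CBT, ingestible
capsule, 15-s sampling), proximal back skin temperature (PBT, 3 sensors,
1-min sampling), mattress surface temperature (MAT, 5 sensors, 1-min
sampling) and ECG-derived heart rate recorded over 450 min after lights-off.
The scientific questions are whether conductive body cooling increases
slow-wave sleep (N3), whether the effect is carried by the core-to-skin heat
flow (indexed by the CBT−PBT gradient), and how the effect distributes over
the ~110-min NREM-REM sleep cycle.

Because the original raw recordings are not publicly available, the package
ships a first-class synthetic cohort generator whose defaults encode the
published summary statistics of the three study samples (n = 15/33/24). All
downstream analysis code is agnostic to whether data came from the generator
or from CSV files in the documented formats.

# Analysis pipeline

1. **Aggregation.** Hypnograms (900 AASM 30-s epochs) and physiology are
   aggregated to 45 ten-minute bins (0-based, half-open `[10b, 10(b+1))`).
   Wake and N1 are pooled. Stage minutes sum to exactly 10 per bin. Sensor
   channels are pooled with equal weight; a bin with fewer than half its
   expected samples is invalid; a variable missing entirely propagates as a
   reduced per-variable N.
2. **Paired deltas.** All inference is on within-subject HM−LM differences
   (Δ). Deltas use only bins valid in both nights, so swapping conditions
   negates every statistic. The night splits at 190 min (the approximate
   time of the maximal core cooling), with the boundary bin assigned to the
   second part: first part bins 0–18, second part bins 19–44.
3. **Per-bin tests.** One-sample two-sided t tests of mean Δ = 0 per bin,
   Benjamini–Hochberg adjusted across the 45 bins of one variable (the FDR
   family is one panel, not all variables jointly). A cumulative-sum variant
   accumulates Δ over bins before testing, to detect small persistent
   effects.
4. **Condition test.** The two-level within-subject mattress factor is
   tested by classical repeated-measures ANOVA; for two levels F equals the
   squared paired t exactly, which the tests verify. η² = SS_condition /
   SS_total. Study enters as a descriptive between-subject stratum.
5. **Cycle period.** Per-subject timecourses of bins 1–44 (the first 10 min
   are omitted) are linearly detrended and Fourier transformed; power is the
   squared amplitude `(|X_k| / (n/2))²`, so a unit-amplitude on-grid cosine
   has peak power 1. The group peak frequency is searched over periods no
   longer than half the night, ties toward the lower frequency. No taper, no
   zero padding: the grid frequency 4/440 = 0.0091 min⁻¹ (period 110 min) is
   exactly representable.
6. **Folding and cosinor.** The 440-min window is folded into 4 cycles of 11
   bins, origin at minute 10 for every subject (no per-subject alignment).
   Per subject, `y = M + β cos(ωt) + γ sin(ωt)` is fitted by least squares;
   the population layer averages `(M, β, γ)` and tests rhythmicity with the
   Hotelling-type zero-amplitude test `F = ((n−2)/(2(n−1))) T²` on `(β, γ)`.
   Phase differences are wrapped to (−55, +55] and summarised by mean, SD,
   paired t and Cohen's d. Wrapping (rather than full circular statistics)
   is valid because the observed separations (~45 min) sit well inside the
   boundary.
7. **Mediation.** Single-mediator linear mediation ΔCBT → ΔPBT → outcome
   with OLS paths, percentile bootstrap over subjects (default 1000
   resamples), bootstrap p = 2·min(P(est ≤ 0), P(est ≥ 0)). The identity
   total = direct + indirect holds exactly on point estimates; ACME is
   invariant under rescaling of the mediator.
8. **Heterogeneity.** Median split by the nightly mean ΔCBT-PBT (values at
   or above the median are "large"); study balance across the split is
   tested with the likelihood-ratio G² test; folded-cycle and cosinor
   analyses are rerun per subgroup with an 11-bin FDR family.

# The synthetic cohort: what it emulates

**Hypnograms** come from a softmax stage-propensity model at 1-min
resolution: baseline log-propensities set so the night-average stage mix
matches the published nocturnal means (W+N1 / N2 / N3 / REM ≈ 2.33 / 4.30 /
1.68 / 1.62 min per 10 min), plus a sleep-onset wake term decaying with a
15-min constant, a cosine cycle term (period 110 min, cycles starting at
minute 10), and linear night trends (N3 declining, REM rising). Sticky
sampling (probability `persistence = 0.6` of repeating the previous minute)
smooths bouts; each minute expands to two 30-s epochs, so bouts are ≥ 1 min.

**Physiology** is built from deterministic signal functions plus Gaussian
noise. On LM nights PBT and MAT rise exponentially after lights-off while HR
drops quickly and CBT declines slowly. The HM night subtracts a conductive
cooling pulse `exp(−t/600) − exp(−t/τ)`, normalised to unit nightly mean,
with onset constants τ = 15/45/90 min for MAT/PBT/CBT — this forces the
HM−LM minima into the observed rank order (MAT ≈ 57 min, PBT ≈ 126 min,
CBT ≈ 200 min, matching the reported latest core minimum near 190 min). HR
is coupled to the CBT signal only (15 bpm/°C, chosen so a −0.15 °C core
delta yields ≈ −2.3 bpm), so the HM−LM heart-rate difference is exactly the
slope times the core difference when noise is off.

**Heterogeneity** enters through one scalar per subject: `g_i ~ N(0.29,
0.45²) °C`, the HM-induced increase of the nocturnal mean CBT−PBT gradient.
Four mechanisms scale with it:

* the skin cooling amplitude (the core amplitude is mostly population-level,
  `cbt_coupling = 0.15`, and the skin absorbs the rest so the nightly
  gradient delta equals `g_i` exactly — chosen because in the published
  correlation matrix the core delta is essentially uncorrelated with the
  sleep effects while the skin delta carries them);
* conversion of second-night-part sleep minutes into N3, in expectation
  exactly `hm_n3_gain · g_i` minutes (default 12 min/°C, the regression
  slope implied by the published r = 0.425 with the published SDs),
  drawing preferentially from REM (weight 20:1), which reproduces both the
  mean REM loss and its negative correlation with the gradient;
* a cycle phase advance (8 min at the mean response); and
* an N3-specific cycle-amplitude boost (doubling at the mean response) that
  is made mean-preserving by numerically offsetting the N3 baseline, so the
  boost reshapes the cycle without adding N3 minutes.

A per-night thermal offset shared by core and skin (`night_shared_sd =
0.12 °C`) couples the nightly CBT and PBT deltas — producing the significant
core-to-skin mediation path — while cancelling exactly in the gradient.

Each subject × component (profile, HM/LM hypnogram, HM/LM physiology) draws
from its own derived substream seed, so changing one parameter never
scrambles unrelated draws, and the whole cohort is a deterministic function
of the seed.

**Why both a phase advance and an amplitude boost?** A pure phase shift of a
cosine produces a difference curve whose acrophase sits a quarter period
(27.5 min) away from the stage's own acrophase. The published Δ-N3 acrophase
(8.2 min) is far closer to the N3 stage peak than that, which is only
attainable if the HM effect also deepens the N3 cycle; REM, whose Δ-acrophase
sits mid-cycle, is reproduced by the phase advance alone. The REM propensity
acrophase default (90 min) is additionally the analytic zero of a geometric
confound: the second night part spans 2.36 cycles, so a response-scaled
phase advance otherwise adds a gradient-correlated REM term that would mask
the conversion-driven REM loss.

# What a green test does and does not establish

The generator reproduces, at the default 72-subject size: the nocturnal
summary means and SDs (approximately; the published nightly ΔN3 SD is
21.6 min, the generator gives ≈ 23), the second-part-only correlation
structure, the 0.0091 min⁻¹ spectral peak, the Δ-acrophases near 8 and
52 min with ≈ 45-min separation, the mediation pattern (indirect core →
skin → N3, direct core → HR), and median-split localisation of the cycle
effects. It does not emulate: real bout-duration distributions (bouts are
shorter than real sleep bouts), sleep-onset REM latency rules, EEG
microstructure, covariate (age/sex/BMI) effects beyond study-level stage
offsets, ambient microclimate or sweating, or missing-data patterns (all
synthetic nights are complete; the missingness rules are exercised by unit
fixtures instead). The gradient–ΔREM correlation is directionally negative
but weaker than the published −0.30; the residual clamp nonlinearity of the
phase advance is the cause, and the corresponding test asserts the sign via
the across-seed mean rather than the magnitude.

# Numerical choices and degenerate inputs

* Per-bin tests need ≥ 3 subjects; smaller bins are excluded and flagged.
* `cohens_d_paired` signals SD = 0 instead of returning Inf.
* The acrophase is undefined (NA, excluded pairwise downstream) when the
  fitted amplitude is below 1e-6 of the series SD or the series is constant;
  a wrap guard maps values within 1e-9 of the period to 0.
* The rhythmicity test returns p = 1 on a degenerate coefficient cloud with
  zero mean, and errors otherwise.
* `mediate` rejects |cor(X, M)| > 0.999 and resamples that become degenerate
  fall back to the point estimates.
* The median-split tie rule is "≥ median → large" (ties have probability 0
  for continuous data).
* G² treats zero observed cells as contributing 0 and rejects zero margins.
* Night-part boundary minute 190 belongs to the second part (half-open
  convention throughout).
* Hypnograms must have exactly 900 30-s epochs; other epoch lengths are
  rejected, not resampled.

# Tolerances used in testing

Exact identities (Parseval normalisation, F = t², mediation decomposition,
noise-free cosinor recovery) are tested at 1e-9. Monte-Carlo recoveries use
bands fixed before the tests were finalised: the conversion-gain slope
12 ± 5 min/°C over three 200-subject cohorts; Δ-acrophases within 12 min of
the published 8.2 / 54.3 with separation 46 ± 10 min over six default
cohorts; null-calibration over 100 zero-effect cohorts bounded by the
nominal q plus two binomial standard errors. Runtime-driven scale-downs
(20-subject null cohorts, 20-seed cumulative-sum majority vote) are noted in
the test files; they change Monte-Carlo resolution, not the criteria.

# Known limitations

The classical replacements (per-bin paired t + BH instead of a mixed model;
population-mean cosinor instead of a mixed-effects cosinor) coincide with
the original machinery only in the balanced two-level case. Unshrunk
per-subject acrophase estimates on noisy Δ-curves make the per-subject phase
difference SD much larger than the published mixed-model value, so the
pipeline's phase-difference d on synthetic data is not comparable to the
published d (the published d values are verified from their printed
summaries instead). No BCa bootstrap, no X×M interaction, no per-subject
cycle segmentation, and no EDF parsing (CSV interchange only) — all by
design.
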