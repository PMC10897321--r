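Package: coolsleep
Title: Crossover Analysis of Conductive Body Cooling Effects on Sleep Architecture
Version: 0.1.0
Authors@R: person("coolsleep", "developers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-night mattress crossover studies of
    conductive body cooling during sleep. Provides a synthetic cohort
    generator for paired hypnograms and physiological series (core body
    temperature, proximal back skin temperature, mattress temperature,
    heart rate), aggregation to a 45 x 10-minute analysis grid, paired
    per-bin testing with Benjamini-Hochberg false discovery rate control,
    cumulative-sum timecourse analysis, periodogram-based NREM-REM cycle
    period estimation, cycle folding, population-mean cosinor fitting with
    rhythmicity testing, single-mediator causal mediation with bootstrap
    confidence intervals, and median-split heterogeneity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
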