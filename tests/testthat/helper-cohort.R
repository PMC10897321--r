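# Shared fixtures, all generated in code. The default cohort and the
# multi-seed effect summary are expensive, so they are memoised for the run.

.fixtures <- new.env(parent = emptyenv())

# Default 72-subject cohort with physiology (the "stated world"), seed 42.
default_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(cohort_spec(seed = 42L))
    .fixtures$binned <- bin_cohort(.fixtures$cohort)
    .fixtures$deltas <- delta_cohort(.fixtures$binned)
  }
  .fixtures$cohort
}
default_binned <- function() { default_cohort(); .fixtures$binned }
default_deltas <- function() { default_cohort(); .fixtures$deltas }

# Spec with every HM effect switched off (and no night-to-night physiology
# drift): HM and LM nights are exchangeable.
null_spec <- function(seed, study_sizes = c(7L, 7L, 6L), ...) {
  cohort_spec(seed = seed, study_sizes = study_sizes,
              hm_gradient_mean = 0, hm_gradient_sd = 0,
              hm_n3_gain = 0, hm_phase_advance_min = 0, hm_n3_amp_gain = 0,
              ...)
}

# Conversion-only spec: the N3 gain parameter is the single HM sleep
# mechanism, so its value is identifiable from the delta-N3-on-g slope.
conversion_only_spec <- function(seed, study_sizes = c(70L, 70L, 60L)) {
  cohort_spec(seed = seed, study_sizes = study_sizes,
              hm_phase_advance_min = 0, hm_n3_amp_gain = 0)
}

# Effect-on summary over several full cohorts (correlation signs, mediation,
# cosinor phase separation); memoised because each cohort is costly.
effect_cohort_stats <- function(n_seeds = 6L) {
  if (!is.null(.fixtures$effect_stats)) return(.fixtures$effect_stats)
  rows <- lapply(seq_len(n_seeds), function(i) {
    co <- generate_cohort(cohort_spec(seed = 400L + i))
    d <- delta_cohort(bin_cohort(co))
    grad <- vapply(d, function(x) x$nightly[["gradient"]], 0)
    pbt <- vapply(d, function(x) x$nightly[["pbt"]], 0)
    n3p2 <- vapply(d, function(x) x$part2[["n3"]], 0)
    remp2 <- vapply(d, function(x) x$part2[["rem"]], 0)
    X <- vapply(d, function(x) x$part2[["cbt"]], 0)
    M <- vapply(d, function(x) x$part2[["pbt"]], 0)
    m_n3 <- mediate(X, M, n3p2, n_boot = 500L, seed = 1L)
    m_hr <- mediate(X, M, vapply(d, function(x) x$part2[["hr"]], 0),
                    n_boot = 500L, seed = 1L)
    cn3 <- population_cosinor(fold_cohort(d, "n3"))
    cre <- population_cosinor(fold_cohort(d, "rem"))
    a3 <- cn3$acrophase
    if (a3 > 55) a3 <- a3 - 110
    list(r_grad_n3 = pearson(grad, n3p2)$r,
         r_grad_n3_p1 = pearson(grad, vapply(d, function(x) x$part1[["n3"]], 0))$r,
         r_pbt_n3 = pearson(pbt, n3p2)$r,
         r_grad_rem = pearson(grad, remp2)$r,
         acme_n3_p = m_n3$p[["indirect"]],
         ade_n3_ci = m_n3$ci["direct", ],
         ade_hr_p = m_hr$p[["direct"]],
         acro_n3 = a3, acro_rem = cre$acrophase,
         separation = coolsleep:::wrap_phase(cre$acrophase - cn3$acrophase))
  })
  .fixtures$effect_stats <- rows
  rows
}

# Brute-force Benjamini-Hochberg step-up, written independently of
# stats::p.adjust: find the largest k with p_(k) <= k q / m by direct
# enumeration, and return the adjusted values via the cumulative-minimum
# definition evaluated literally.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {          # adjusted p_(i) = min_{j >= i} m p_(j) / j
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, 0)
    adj[o[i]] <- min(1, min(cand))
  }
  adj
}

# A deterministic 900-epoch hypnogram built from per-bin epoch counts
# (counts: list of c(W, N1, N2, N3, REM) per 20-epoch bin, recycled).
build_hypnogram <- function(counts) {
  stages <- c("W", "N1", "N2", "N3", "REM")
  unlist(lapply(seq_len(45), function(b) {
    cnt <- counts[[(b - 1L) %% length(counts) + 1L]]
    stopifnot(sum(cnt) == 20L)
    rep(stages, times = cnt)
  }))
}

# Minimal physio data frame with constant values per variable.
constant_physio <- function(cbt = 36.5, pbt = 34.5, mat = 31, hr = 60) {
  t_cbt <- seq(0, 26985, by = 15)
  t_skin <- seq(0, 26940, by = 60)
  t_hr <- seq(0, 26999, by = 1)
  rbind(
    data.frame(variable = "cbt", sensor_id = "cbt1", time_s = t_cbt, value = cbt),
    do.call(rbind, lapply(1:3, function(s)
      data.frame(variable = "pbt", sensor_id = paste0("pbt", s),
                 time_s = t_skin, value = pbt))),
    do.call(rbind, lapply(1:5, function(s)
      data.frame(variable = "mat", sensor_id = paste0("mat", s),
                 time_s = t_skin, value = mat))),
    data.frame(variable = "hr", sensor_id = "hr1", time_s = t_hr, value = hr))
}

# Wrap a binned data frame as a binned_timecourse with metadata.
as_bt <- function(df, subject = "S1", study = 1L, condition = "HM") {
  structure(df, class = c("binned_timecourse", "data.frame"),
            subject_id = subject, study = study, condition = condition)
}
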