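#' Specification of a synthetic paired-night cohort
#'
#' Builds the parameter object that fully determines a synthetic crossover
#' cohort: three study subpopulations, each subject sleeping one night on a
#' high-heat-capacity (HM, cooling) and one on a low-heat-capacity (LM,
#' regular) mattress. Defaults reproduce the stated world of the analysed
#' three-centre study: n = 15/33/24 subjects, a ~110-min NREM-REM cycle with
#' N3 early and REM late both within each cycle and across the night,
#' exponential conductive-cooling kinetics with decline-rate rank order
#' MAT > PBT > CBT, heart rate linearly coupled to core temperature, and
#' between-subject heterogeneity of the cooling response through a scalar
#' per-subject gradient gain \code{g_i} that drives both the temperature and
#' the N3 effects (inducing the positive second-night-part correlation
#' between the CBT-PBT gradient change and the N3 change).
#'
#' @param study_sizes Integer vector of three subject counts.
#' @param seed Integer seed; fully determines the cohort.
#' @param cycle_period_min NREM-REM cycle period in minutes.
#' @param n3_cycle_amplitude,rem_cycle_amplitude Cycle modulation depth of the
#'   N3 / REM stage propensities (log-score units).
#' @param n3_acrophase_min,rem_acrophase_min Within-cycle acrophase of the N3
#'   and REM propensity cosines, minutes after cycle start (cycles start at
#'   minute 10 after lights-off).
#' @param n3_night_decline,rem_night_rise Linear night trends of the N3 / REM
#'   propensities, score units per minute (N3 declining, REM rising).
#' @param persistence Per-minute probability of keeping the previous stage
#'   (bout smoothing); 1 yields a single-stage night.
#' @param hm_gradient_mean,hm_gradient_sd Mean and SD (deg C) of the
#'   per-subject HM-induced increase \code{g_i} of the nocturnal mean
#'   CBT-PBT gradient.
#' @param hm_n3_gain Minutes of extra N3 in the second night part per deg C
#'   of gradient increase.
#' @param hm_phase_advance_min Cycle phase advance (minutes) of the N3/REM
#'   propensity rhythm on HM for a subject with \code{g_i = hm_gradient_mean}
#'   (scales with \code{g_i}).
#' @param hm_n3_amp_gain Fractional gain of the N3 cycle amplitude on HM for
#'   a subject with \code{g_i = hm_gradient_mean} (scales with \code{g_i});
#'   the deep-sleep boost that places the N3 effect near the N3 peak of the
#'   cycle while the REM effect stays phase-advance dominated.
#' @param temp_baselines Named numeric: pre-rise baselines (deg C) for
#'   \code{cbt}, \code{pbt}, \code{mat}.
#' @param tau_mat,tau_pbt,tau_cbt Exponential onset time constants (minutes)
#'   of the HM cooling pulse; must satisfy \code{tau_mat < tau_pbt < tau_cbt},
#'   which forces the rank order of the HM-LM minima (MAT first, CBT last).
#' @param tau_recovery Shared slow recovery constant (minutes) of the cooling
#'   pulse (temperatures drift back after the conductive-loss maximum).
#' @param hr_baseline Heart-rate baseline (bpm).
#' @param hr_cbt_slope Heart-rate coupling to core temperature (bpm per deg C).
#' @param noise_sd Named numeric of per-sample measurement noise SDs
#'   (\code{cbt}, \code{pbt}, \code{mat} in deg C, \code{hr} in bpm).
#' @param night_offset_sd Named numeric of independent night-to-night
#'   physiological baseline SDs (deg C) for \code{cbt}, \code{pbt}, \code{mat}.
#' @param night_shared_sd SD (deg C) of a night-level thermal offset shared by
#'   core and skin: it couples the nightly CBT and PBT deltas (the core-to-skin
#'   path of the mediation) while cancelling exactly in the CBT-PBT gradient.
#' @param subject_sd Named numeric of between-subject baseline SDs
#'   (\code{cbt}, \code{pbt}, \code{mat}, \code{hr}).
#' @param mat_coupling Fraction of the gradient heterogeneity passed through
#'   to the mattress-surface cooling amplitude (the MAT response is far less
#'   heterogeneous than the body response).
#' @param cbt_coupling Fraction of the gradient heterogeneity passed through
#'   to the core cooling amplitude. Small by design: the core delta is nearly
#'   uncorrelated with the sleep effects while the skin delta carries them,
#'   so the skin response absorbs the remaining heterogeneity (the nightly
#'   gradient delta equals \code{g_i} exactly).
#' @param epoch_s Hypnogram epoch length, seconds (fixed AASM 30 s).
#' @param night_min Night length after lights-off, minutes.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(study_sizes = c(15L, 33L, 24L),
                        seed = 1L,
                        cycle_period_min = 110,
                        n3_cycle_amplitude = 0.9,
                        rem_cycle_amplitude = 0.9,
                        n3_acrophase_min = 37,
                        rem_acrophase_min = 90,
                        n3_night_decline = 0.003,
                        rem_night_rise = 0.003,
                        persistence = 0.6,
                        hm_gradient_mean = 0.29,
                        hm_gradient_sd = 0.45,
                        hm_n3_gain = 12,
                        hm_phase_advance_min = 8,
                        hm_n3_amp_gain = 1,
                        temp_baselines = c(cbt = 36.70, pbt = 33.5, mat = 28.0),
                        tau_mat = 15,
                        tau_pbt = 45,
                        tau_cbt = 90,
                        tau_recovery = 600,
                        hr_baseline = 62.5,
                        hr_cbt_slope = 15,
                        noise_sd = c(cbt = 0.05, pbt = 0.15, mat = 0.20, hr = 1.5),
                        night_offset_sd = c(cbt = 0.09, pbt = 0.05, mat = 0.30),
                        night_shared_sd = 0.12,
                        subject_sd = c(cbt = 0.19, pbt = 0.50, mat = 0.80, hr = 8.5),
                        mat_coupling = 0.3,
                        cbt_coupling = 0.15,
                        epoch_s = 30,
                        night_min = 450) {
  spec <- list(
    study_sizes = as.integer(study_sizes), seed = as.integer(seed),
    cycle_period_min = cycle_period_min,
    n3_cycle_amplitude = n3_cycle_amplitude,
    rem_cycle_amplitude = rem_cycle_amplitude,
    n3_acrophase_min = n3_acrophase_min,
    rem_acrophase_min = rem_acrophase_min,
    n3_night_decline = n3_night_decline,
    rem_night_rise = rem_night_rise,
    persistence = persistence,
    hm_gradient_mean = hm_gradient_mean,
    hm_gradient_sd = hm_gradient_sd,
    hm_n3_gain = hm_n3_gain,
    hm_phase_advance_min = hm_phase_advance_min,
    hm_n3_amp_gain = hm_n3_amp_gain,
    temp_baselines = temp_baselines,
    tau_mat = tau_mat, tau_pbt = tau_pbt, tau_cbt = tau_cbt,
    tau_recovery = tau_recovery,
    hr_baseline = hr_baseline, hr_cbt_slope = hr_cbt_slope,
    noise_sd = noise_sd, night_offset_sd = night_offset_sd,
    night_shared_sd = night_shared_sd,
    subject_sd = subject_sd, mat_coupling = mat_coupling,
    cbt_coupling = cbt_coupling,
    epoch_s = epoch_s, night_min = night_min)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (length(spec$study_sizes) != 3L || any(spec$study_sizes <= 0L))
    stop("study_sizes: must be three positive counts")
  if (!(spec$tau_mat < spec$tau_pbt && spec$tau_pbt < spec$tau_cbt))
    stop("tau_mat/tau_pbt/tau_cbt: time constants must satisfy tau_mat < tau_pbt < tau_cbt")
  if (spec$persistence < 0 || spec$persistence > 1)
    stop("persistence: must lie in [0, 1]")
  if (spec$epoch_s != 30)
    stop("epoch_s: only 30-s (AASM) epochs are supported")
  if (spec$night_min <= 10)
    stop("night_min: must exceed 10 minutes")
  if (((spec$night_min - 10) %% spec$cycle_period_min) != 0)
    stop("cycle_period_min: must divide the folding window (night_min - 10)")
  for (nm in c("cbt", "pbt", "mat"))
    if (is.na(spec$temp_baselines[nm])) stop("temp_baselines: missing ", nm)
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", sum(x$study_sizes), "subjects in studies",
      paste(x$study_sizes, collapse = "/"),
      sprintf("| cycle %g min | g ~ N(%.2f, %.2f) | seed %d\n",
              x$cycle_period_min, x$hm_gradient_mean, x$hm_gradient_sd, x$seed))
  invisible(x)
}

# Per-subject latent profile: the scalar cooling response g_i plus stable
# baseline offsets (shared by both nights, so they cancel in HM-LM deltas)
# and study-level stage-propensity offsets.
draw_profile <- function(spec, subject_index, study) {
  set.seed(substream_seed(spec$seed, subject_index, 0L))
  study_n3  <- c(0.25, -0.15, 0)[study]
  study_rem <- c(0.25, -0.15, 0)[study]
  list(
    subject_id = sprintf("S%d_%02d", study, subject_index),
    study = study,
    g_i = stats::rnorm(1, spec$hm_gradient_mean, spec$hm_gradient_sd),
    base_offsets = c(
      cbt = stats::rnorm(1, 0, spec$subject_sd[["cbt"]]),
      pbt = stats::rnorm(1, 0, spec$subject_sd[["pbt"]]),
      mat = stats::rnorm(1, 0, spec$subject_sd[["mat"]]),
      hr  = stats::rnorm(1, 0, spec$subject_sd[["hr"]])),
    pbt_sensor_offsets = stats::rnorm(3, 0, 0.3),
    mat_sensor_offsets = stats::rnorm(5, 0, 0.3),
    stage_offsets = c(n3 = study_n3, rem = study_rem))
}
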