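# Synthetic cohort generation: hypnograms via a softmax stage-propensity
# model (cosine ultradian modulation + linear night trends + persistence
# smoothing), physiology via exponential conductive-cooling kinetics.

STAGES <- c("W", "N1", "N2", "N3", "REM")
# Baseline log-propensities chosen so night-average stage proportions land
# near the regular-mattress nocturnal means (2.33 / 4.30 / 1.68 / 1.62
# min/10 min for W+N1 / N2 / N3 / REM).
BASE_SCORES <- log(c(W = 0.130, N1 = 0.103, N2 = 0.430, N3 = 0.168, REM = 0.162))

# HM cycle phase advance for a given subject: scales with the subject's
# cooling response relative to the population mean, clamped to a quarter
# period so the advance stays interpretable.
phase_advance <- function(profile, condition, spec) {
  if (condition != "HM" || spec$hm_phase_advance_min == 0) return(0)
  scale <- if (spec$hm_gradient_mean != 0) profile$g_i / spec$hm_gradient_mean else 1
  max(-spec$cycle_period_min / 4,
      min(spec$cycle_period_min / 4, spec$hm_phase_advance_min * scale))
}

# N3 cycle-amplitude multiplier on HM (deep-sleep boost), scaling with the
# subject's relative cooling response; floored so the cycle never inverts.
n3_amp_multiplier <- function(profile, condition, spec) {
  if (condition != "HM" || spec$hm_n3_amp_gain == 0) return(1)
  scale <- if (spec$hm_gradient_mean != 0) profile$g_i / spec$hm_gradient_mean else 1
  max(0.1, 1 + spec$hm_n3_amp_gain * scale)
}

#' Generate one night's hypnogram
#'
#' Stage labels are drawn per minute from a softmax over stage scores
#' (baseline + cosine cycle term + linear night trend + condition terms),
#' with sticky sampling (probability \code{persistence} of repeating the
#' previous minute's stage) and each minute expanded to two 30-s epochs, so
#' bouts are always >= 1 min. On the HM night the cycle phase is advanced by
#' the subject's scaled \code{hm_phase_advance_min} and, in the second night
#' part (>= 190 min), non-N3 sleep minutes are converted to N3 with a
#' probability calibrated so the expected extra N3 equals
#' \code{hm_n3_gain * g_i} minutes.
#'
#' @param profile Subject profile from the cohort generator.
#' @param condition "HM" or "LM".
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for this night's stage stream.
#' @return Character vector of 900 stage labels in W/N1/N2/N3/REM.
#' @export
generate_hypnogram <- function(profile, condition, spec, seed) {
  condition <- match.arg(condition, c("HM", "LM"))
  set.seed(as.integer(seed %% 2147483629))
  n_min <- spec$night_min
  t <- seq_len(n_min) - 0.5            # minute midpoints after lights-off
  omega <- 2 * pi / spec$cycle_period_min
  adv <- phase_advance(profile, condition, spec)

  scores <- matrix(rep(BASE_SCORES, each = n_min), nrow = n_min,
                   dimnames = list(NULL, STAGES))
  scores[, "W"] <- scores[, "W"] + 1.5 * exp(-t / 15)   # sleep-onset wake
  tc <- t - n_min / 2                                    # centred trend
  n3_cos <- cos(omega * (t - 10 - (spec$n3_acrophase_min - adv)))
  amp_mult <- n3_amp_multiplier(profile, condition, spec)
  scores[, "N3"] <- scores[, "N3"] + profile$stage_offsets[["n3"]] +
    amp_mult * spec$n3_cycle_amplitude * n3_cos -
    spec$n3_night_decline * tc
  if (amp_mult != 1) {
    # Mean-preserving boost: offset the N3 baseline so the amplitude gain
    # reshapes the cycle without inflating expected N3 minutes (softmax is
    # convex in the score); hm_n3_gain stays the sole source of mean delta.
    ref <- scores
    ref[, "N3"] <- ref[, "N3"] - (amp_mult - 1) * spec$n3_cycle_amplitude * n3_cos
    target <- mean(softmax_rows(ref)[, "N3"])
    shift <- stats::uniroot(function(s) {
      sc <- scores
      sc[, "N3"] <- sc[, "N3"] + s
      mean(softmax_rows(sc)[, "N3"]) - target
    }, c(-12, 12), extendInt = "yes", tol = 1e-8)$root
    scores[, "N3"] <- scores[, "N3"] + shift
  }
  scores[, "REM"] <- scores[, "REM"] + profile$stage_offsets[["rem"]] +
    spec$rem_cycle_amplitude *
      cos(omega * (t - 10 - (spec$rem_acrophase_min - adv))) +
    spec$rem_night_rise * tc

  prob <- softmax_rows(scores)
  stage <- integer(n_min)
  keep <- stats::runif(n_min) < spec$persistence
  stage[1L] <- sample.int(5L, 1L, prob = prob[1L, ])
  for (m in 2:n_min) {
    stage[m] <- if (keep[m]) stage[m - 1L]
                else sample.int(5L, 1L, prob = prob[m, ])
  }

  if (condition == "HM" && spec$hm_n3_gain != 0 && profile$g_i != 0) {
    target <- spec$hm_n3_gain * profile$g_i      # minutes of N3 to add/remove
    second <- which(t >= 190)
    if (target > 0) {
      # Deepening converts non-N3 sleep to N3, drawing preferentially from
      # REM (weight 20 vs 1): the ratio of the REM loss to the N3 gain per
      # deg C implied by the nocturnal-mean deltas (-2.7 vs +7.5 min at a
      # +0.29 deg C gradient) and the negative second-part gradient-REM
      # correlation both put the REM share of the converted minutes near 3/4.
      cand <- second[stage[second] %in% c(2L, 3L, 5L)]   # N1, N2, REM
      if (length(cand)) {
        w <- ifelse(stage[cand] == 5L, 20, 1)
        p <- pmin(1, target * w / sum(w))
        stage[cand[stats::runif(length(cand)) < p]] <- 4L
      }
    } else {
      cand <- second[stage[second] == 4L]
      if (length(cand)) {
        p <- min(1, -target / length(cand))
        stage[cand[stats::runif(length(cand)) < p]] <- 3L
      }
    }
  }

  rep(STAGES[stage], each = 2L)
}

# Normalised cooling pulse: rises with time constant tau, relaxes with the
# shared recovery constant; scaled to unit nightly mean so per-variable
# amplitude coefficients are nightly-mean deltas per deg C of gradient gain.
cooling_shape <- function(t_min, tau, spec) {
  T <- spec$night_min
  m <- function(tt) (tt / T) * (1 - exp(-T / tt))
  raw_mean <- m(spec$tau_recovery) - m(tau)
  (exp(-t_min / spec$tau_recovery) - exp(-t_min / tau)) / raw_mean
}

# Nightly-mean HM-LM cooling amplitudes, from the observed ratios of the
# nocturnal-mean deltas to the gradient delta (-0.15 / -2.80 per +0.29 degC).
# The core response is mostly population-level (cbt_coupling of the subject
# heterogeneity), the skin response absorbs the rest so the nightly gradient
# delta equals g_i exactly: the crossover correlation structure has the
# gradient effect carried by the skin, not the core.
COOL_COEF <- c(cbt = 0.15 / 0.29, mat = 2.80 / 0.29)

# Per-subject nightly-mean cooling amplitudes (deg C) for CBT and PBT.
cooling_amplitudes <- function(profile, condition, spec) {
  if (condition != "HM") return(c(cbt = 0, pbt = 0))
  c_cbt <- COOL_COEF[["cbt"]] *
    (spec$hm_gradient_mean +
       spec$cbt_coupling * (profile$g_i - spec$hm_gradient_mean))
  c(cbt = c_cbt, pbt = c_cbt + profile$g_i)
}

# Deterministic (noise-free) physiological signal at minutes t_min.
physio_signal <- function(var, t_min, profile, condition, spec, night_offsets) {
  tb <- spec$temp_baselines
  amp <- cooling_amplitudes(profile, condition, spec)
  g_mat <- if (condition == "HM")
    spec$hm_gradient_mean + spec$mat_coupling * (profile$g_i - spec$hm_gradient_mean)
  else 0
  cbt_dev <- function(tt)            # CBT deviation shared with HR coupling
    night_offsets[["cbt"]] - 0.18 * (1 - exp(-tt / 90)) -
      amp[["cbt"]] * cooling_shape(tt, spec$tau_cbt, spec)
  switch(var,
    cbt = tb[["cbt"]] + profile$base_offsets[["cbt"]] + cbt_dev(t_min),
    pbt = tb[["pbt"]] + profile$base_offsets[["pbt"]] + night_offsets[["pbt"]] +
      1.6 * (1 - exp(-t_min / 30)) -
      amp[["pbt"]] * cooling_shape(t_min, spec$tau_pbt, spec),
    mat = tb[["mat"]] + profile$base_offsets[["mat"]] + night_offsets[["mat"]] +
      5.8 * (1 - exp(-t_min / 20)) -
      COOL_COEF[["mat"]] * g_mat * cooling_shape(t_min, spec$tau_mat, spec),
    hr = spec$hr_baseline + profile$base_offsets[["hr"]] +
      6 * exp(-t_min / 30) + spec$hr_cbt_slope * cbt_dev(t_min),
    stop("unknown variable ", var))
}

#' Generate one night's physiological series
#'
#' Core body temperature sampled every 15 s, three proximal-back-skin and
#' five mattress sensors every 60 s, heart rate every 1 s, all over the
#' 450-min night. LM nights show the characteristic sleep-onset pattern
#' (PBT/MAT rise, fast HR drop, slow CBT decline); HM nights additionally
#' subtract a \code{g_i}-scaled conductive-cooling pulse whose onset time
#' constants satisfy tau_mat < tau_pbt < tau_cbt, so the HM-LM minima occur
#' in the order MAT, PBT, CBT. HR is coupled only to the CBT signal
#' (\code{hr_cbt_slope} bpm per deg C), so with zero noise the HM-LM heart
#' rate difference is exactly slope times the CBT difference.
#'
#' @inheritParams generate_hypnogram
#' @param seed Integer seed for this night's physiology stream.
#' @return Data frame with columns variable, sensor_id, time_s, value.
#' @export
generate_physiology <- function(profile, condition, spec, seed) {
  condition <- match.arg(condition, c("HM", "LM"))
  set.seed(as.integer(seed %% 2147483629))
  nsd <- spec$noise_sd
  no_sd <- spec$night_offset_sd
  shared <- stats::rnorm(1, 0, spec$night_shared_sd)   # warm vs cool night
  night_offsets <- c(cbt = shared + stats::rnorm(1, 0, no_sd[["cbt"]]),
                     pbt = shared + stats::rnorm(1, 0, no_sd[["pbt"]]),
                     mat = stats::rnorm(1, 0, no_sd[["mat"]]))
  end_s <- spec$night_min * 60
  out <- list()

  t_cbt <- seq(0, end_s - 1, by = 15)
  out$cbt <- data.frame(variable = "cbt", sensor_id = "cbt1", time_s = t_cbt,
    value = physio_signal("cbt", t_cbt / 60, profile, condition, spec, night_offsets) +
      stats::rnorm(length(t_cbt), 0, nsd[["cbt"]]))

  t_skin <- seq(0, end_s - 1, by = 60)
  for (s in 1:3) {
    out[[paste0("pbt", s)]] <- data.frame(
      variable = "pbt", sensor_id = paste0("pbt", s), time_s = t_skin,
      value = physio_signal("pbt", t_skin / 60, profile, condition, spec, night_offsets) +
        profile$pbt_sensor_offsets[s] +
        stats::rnorm(length(t_skin), 0, nsd[["pbt"]]))
  }
  for (s in 1:5) {
    out[[paste0("mat", s)]] <- data.frame(
      variable = "mat", sensor_id = paste0("mat", s), time_s = t_skin,
      value = physio_signal("mat", t_skin / 60, profile, condition, spec, night_offsets) +
        profile$mat_sensor_offsets[s] +
        stats::rnorm(length(t_skin), 0, nsd[["mat"]]))
  }

  t_hr <- seq(0, end_s - 1, by = 1)
  out$hr <- data.frame(variable = "hr", sensor_id = "hr1", time_s = t_hr,
    value = physio_signal("hr", t_hr / 60, profile, condition, spec, night_offsets) +
      stats::rnorm(length(t_hr), 0, nsd[["hr"]]))

  do.call(rbind, unname(out))
}

night_recording <- function(profile, condition, hypnogram, physio) {
  structure(list(subject_id = profile$subject_id, study = profile$study,
                 condition = condition, hypnogram = hypnogram, physio = physio),
            class = "night_recording")
}

#' Generate a full paired-night synthetic cohort
#'
#' One subject profile per subject (shared by both nights) and two
#' [night_recording]s (HM and LM) each. Each subject and component
#' (hypnogram vs physiology, HM vs LM) draws from its own named random
#' substream, so the output is fully determined by \code{spec$seed}.
#'
#' @param spec A [cohort_spec()].
#' @param physiology If FALSE, skip the physiological series (hypnograms
#'   only; used by large Monte-Carlo calibration runs).
#' @return List of class \code{cohort}; each element has \code{profile},
#'   \code{hm} and \code{lm}.
#' @export
generate_cohort <- function(spec, physiology = TRUE) {
  validate_cohort_spec(spec)
  studies <- rep(1:3, times = spec$study_sizes)
  cohort <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    prof <- draw_profile(spec, i, studies[i])
    hyp_hm <- generate_hypnogram(prof, "HM", spec, substream_seed(spec$seed, i, 1L))
    hyp_lm <- generate_hypnogram(prof, "LM", spec, substream_seed(spec$seed, i, 2L))
    phys_hm <- phys_lm <- NULL
    if (physiology) {
      phys_hm <- generate_physiology(prof, "HM", spec, substream_seed(spec$seed, i, 3L))
      phys_lm <- generate_physiology(prof, "LM", spec, substream_seed(spec$seed, i, 4L))
    }
    cohort[[i]] <- list(profile = prof,
                        hm = night_recording(prof, "HM", hyp_hm, phys_hm),
                        lm = night_recording(prof, "LM", hyp_lm, phys_lm))
  }
  structure(cohort, class = "cohort", spec = spec)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", length(x), "subjects x 2 nights (HM/LM)\n")
  invisible(x)
}
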