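# Synthetic cohort generator: determinism, null symmetry, physiology
# kinetics, hypnogram structure, and the generative correlation.

test_that("spec validation names the offending field", {
  expect_error(cohort_spec(study_sizes = c(0, 3, 4)), "study_sizes")
  expect_error(cohort_spec(tau_mat = 50, tau_pbt = 45), "tau_")
  expect_error(cohort_spec(cycle_period_min = 100), "cycle_period_min")
  expect_error(cohort_spec(epoch_s = 20), "epoch_s")
  expect_error(cohort_spec(persistence = 1.2), "persistence")
})

test_that("the cohort is a deterministic function of the seed", {
  spec1 <- cohort_spec(seed = 1L, study_sizes = c(2L, 2L, 2L))
  c1 <- generate_cohort(spec1)
  c2 <- generate_cohort(spec1)
  expect_identical(c1[[1]]$hm$hypnogram, c2[[1]]$hm$hypnogram)
  expect_identical(c1[[3]]$lm$physio$value, c2[[3]]$lm$physio$value)

  c3 <- generate_cohort(cohort_spec(seed = 2L, study_sizes = c(2L, 2L, 2L)))
  expect_false(identical(c1[[1]]$hm$hypnogram, c3[[1]]$hm$hypnogram))

  expect_equal(length(c1), 6L)
  expect_equal(length(c1[[1]]$hm$hypnogram), 900L)
  expect_true(all(c1[[1]]$hm$physio$time_s >= 0 &
                    c1[[1]]$hm$physio$time_s < 27000))
  temps <- c1[[1]]$hm$physio
  temps <- temps$value[temps$variable %in% c("cbt", "pbt", "mat")]
  expect_true(all(temps > 25 & temps < 40))
})

test_that("with all HM effects off the nightly N3 delta is centred at zero", {
  spec <- null_spec(seed = 9L, study_sizes = c(34L, 33L, 33L))
  co <- generate_cohort(spec, physiology = FALSE)
  d <- delta_cohort(bin_cohort(co))
  n3 <- vapply(d, function(x) x$nightly[["n3"]], 0) * 45
  se <- sd(n3) / sqrt(length(n3))
  expect_lt(abs(mean(n3)), 3.5 * se)             # symmetric by construction
})

test_that("noise-free physiology obeys the stated kinetics", {
  base_args <- list(seed = 77L, study_sizes = c(1L, 1L, 1L),
                    noise_sd = c(cbt = 0, pbt = 0, mat = 0, hr = 0),
                    night_offset_sd = c(cbt = 0, pbt = 0, mat = 0),
                    night_shared_sd = 0,
                    subject_sd = c(cbt = 0, pbt = 0, mat = 0, hr = 0))

  # g = 0 and no noise: HM and LM physiology identical
  spec0 <- do.call(cohort_spec, c(base_args, list(
    hm_gradient_mean = 0, hm_gradient_sd = 0, hm_n3_gain = 0,
    hm_phase_advance_min = 0, hm_n3_amp_gain = 0)))
  co0 <- generate_cohort(spec0)
  expect_equal(co0[[1]]$hm$physio$value, co0[[1]]$lm$physio$value,
               tolerance = 1e-12)

  # g > 0: HM-LM minima occur no later for MAT than PBT than CBT, and the
  # HR delta equals the configured slope times the CBT delta at every sample
  spec1 <- do.call(cohort_spec, c(base_args, list(
    hm_gradient_mean = 0.5, hm_gradient_sd = 0)))
  co1 <- generate_cohort(spec1)
  dmin <- vapply(c("mat", "pbt", "cbt"), function(v) {
    hm <- co1[[1]]$hm$physio
    lm <- co1[[1]]$lm$physio
    sel <- hm$variable == v & hm$sensor_id == hm$sensor_id[hm$variable == v][1]
    diff <- hm$value[sel] - lm$value[sel]
    hm$time_s[sel][which.min(diff)]
  }, 0)
  expect_true(dmin[["mat"]] <= dmin[["pbt"]])
  expect_true(dmin[["pbt"]] <= dmin[["cbt"]])

  hm <- co1[[1]]$hm$physio; lm <- co1[[1]]$lm$physio
  t_cbt <- hm$time_s[hm$variable == "cbt"]
  d_cbt <- hm$value[hm$variable == "cbt"] - lm$value[lm$variable == "cbt"]
  sel_hr <- hm$variable == "hr" & hm$time_s %in% t_cbt
  d_hr <- hm$value[sel_hr] - lm$value[sel_hr]
  expect_equal(d_hr, spec1$hr_cbt_slope * d_cbt, tolerance = 1e-9)
})

test_that("hypnogram propensity model: stationarity, persistence limit, folded peaks", {
  # no cycle terms, no trends, iid draws: stage proportions stationary
  spec_flat <- cohort_spec(seed = 5L, n3_cycle_amplitude = 0,
                           rem_cycle_amplitude = 0, n3_night_decline = 0,
                           rem_night_rise = 0, persistence = 0,
                           hm_n3_gain = 0, hm_phase_advance_min = 0,
                           hm_n3_amp_gain = 0)
  prof <- coolsleep:::draw_profile(spec_flat, 1L, 2L)
  set.seed(100)
  ps <- vapply(1:20, function(i) {
    h <- generate_hypnogram(prof, "LM", spec_flat, seed = 1000 + i)
    h <- h[seq(1, length(h), by = 2)]            # one label per minute (iid here)
    h <- h[h != "W"]                             # sleep-onset wake term decays
    half <- length(h) %/% 2
    lv <- c("N1", "N2", "N3", "REM")
    first <- table(factor(h[1:half], levels = lv))
    second <- table(factor(h[(half + 1):(2 * half)], levels = lv))
    suppressWarnings(chisq.test(rbind(first, second))$p.value)
  }, 0)
  expect_lte(mean(ps < 0.01), 0.25)              # n.s. at alpha = .01 mostly

  # persistence at maximum: a single-stage night
  spec_stick <- cohort_spec(seed = 5L, persistence = 1,
                            hm_n3_gain = 0, hm_phase_advance_min = 0,
                            hm_n3_amp_gain = 0)
  h1 <- generate_hypnogram(prof, "LM", spec_stick, seed = 3L)
  expect_equal(length(unique(h1)), 1L)

  # folded LM stage peaks: N3 early in the cycle, REM late (majority of
  # >= 100 seeds; generator ground truth is bins 2-4 / 8-10)
  spec <- cohort_spec(seed = 5L)
  peaks <- t(vapply(1:100, function(i) {
    h <- generate_hypnogram(prof, "LM", spec, seed = 2000 + i)
    b <- bin_hypnogram(h)
    c(n3 = which.max(fold_cycles(b$n3)$cycle_avg) - 1L,
      rem = which.max(fold_cycles(b$rem)$cycle_avg) - 1L)
  }, c(n3 = 0L, rem = 0L)))
  expect_gt(mean(peaks[, "n3"] %in% 2:4), 0.5)
  expect_gt(mean(peaks[, "rem"] %in% 8:10), 0.5)
})

test_that("the generative model induces the configured gradient-N3 correlation", {
  # Conversion-only world (linear-Gaussian skeleton). Closed-form oracle:
  # r = k sg^2 / (s_grad s_y) with k = hm_n3_gain, s_grad^2 = sg^2 + the
  # analytic night-offset variance of the measured gradient, and s_y^2 =
  # k^2 sg^2 + v0 where v0 is the stage-sampling variance measured on an
  # independent zero-effect cohort.
  spec_null <- null_spec(seed = 88L, study_sizes = c(70L, 70L, 60L))
  co0 <- generate_cohort(spec_null, physiology = FALSE)
  d0 <- delta_cohort(bin_cohort(co0))
  v0 <- var(vapply(d0, function(x) x$part2[["n3"]], 0) * 26)

  spec <- conversion_only_spec(seed = 89L)
  k <- spec$hm_n3_gain
  sg2 <- spec$hm_gradient_sd^2
  grad_noise <- 2 * (spec$night_offset_sd[["cbt"]]^2 +
                       spec$night_offset_sd[["pbt"]]^2)
  r_pred <- k * sg2 / (sqrt(sg2 + grad_noise) * sqrt(k^2 * sg2 + v0))

  co <- generate_cohort(spec)
  d <- delta_cohort(bin_cohort(co))
  grad <- vapply(d, function(x) x$nightly[["gradient"]], 0)
  n3p2 <- vapply(d, function(x) x$part2[["n3"]], 0) * 26
  r_emp <- pearson(grad, n3p2)$r
  expect_gt(r_emp, 0)
  z <- function(r) atanh(r)
  expect_lt(abs(z(r_emp) - z(r_pred)), 3.5 / sqrt(length(d) - 3))
})

test_that("hm_n3_gain is recovered from conversion-only cohorts", {
  slopes <- vapply(1:3, function(i) {
    spec <- conversion_only_spec(seed = 600L + i)
    co <- generate_cohort(spec, physiology = FALSE)
    d <- delta_cohort(bin_cohort(co))
    n3 <- vapply(d, function(x) x$nightly[["n3"]], 0) * 45
    g <- vapply(co, function(s) s$profile$g_i, 0)
    unname(coef(lm(n3 ~ g))[2])
  }, 0)
  expect_gt(mean(slopes), 12 - 5)                # configured 12 min/degC
  expect_lt(mean(slopes), 12 + 5)                # MC se of the mean ~ 2.2
})
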