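# Aggregation to the 10-min grid, nocturnal summaries and paired deltas.

test_that("bin_hypnogram pools W+N1, conserves 10 min per bin and matches a hand count", {
  all_n3 <- rep("N3", 900)
  b <- bin_hypnogram(all_n3)
  expect_equal(b$n3, rep(10, 45))
  expect_equal(b$wn1 + b$n2 + b$rem, rep(0, 45))

  alt <- rep(c("W", "N1"), 450)
  expect_equal(bin_hypnogram(alt)$wn1, rep(10, 45))

  # Hand-counted 40-epoch fixture recycled over the night: per 20-epoch bin
  # 4 W, 2 N1, 7 N2, 4 N3, 3 REM in odd bins and 0/0/13/3/4 in even bins.
  hyp <- build_hypnogram(list(c(4L, 2L, 7L, 4L, 3L), c(0L, 0L, 13L, 3L, 4L)))
  b <- bin_hypnogram(hyp)
  expect_equal(b$wn1[1:2], c(3.0, 0.0))    # (4+2) and 0 epochs x 0.5 min
  expect_equal(b$n2[1:2], c(3.5, 6.5))
  expect_equal(b$n3[1:2], c(2.0, 1.5))
  expect_equal(b$rem[1:2], c(1.5, 2.0))
  expect_true(all(abs(b$wn1 + b$n2 + b$n3 + b$rem - 10) < 1e-9))
  # nightly mean N3 = (23x2.0 + 22x1.5)/45 = 1.756 min/10 min, published scale
  expect_equal(mean(b$n3), (23 * 2.0 + 22 * 1.5) / 45)

  expect_error(bin_hypnogram(rep("N3", 899)), "900 epochs")
  expect_error(bin_hypnogram(c(rep("N3", 899), "N4")), "unknown stage")
})

test_that("bin_physio applies equal-weight sensor pooling, validity and the gradient", {
  ph <- constant_physio(cbt = 36.5, pbt = 34.5)
  b <- bin_physio(ph)
  expect_equal(b$cbt, rep(36.5, 45))
  expect_equal(b$gradient, rep(36.5 - 34.5, 45))

  # one PBT sensor at 34, two at 35 -> pooled mean 34.667
  ph2 <- constant_physio()
  ph2$value[ph2$variable == "pbt" & ph2$sensor_id == "pbt1"] <- 34
  ph2$value[ph2$variable == "pbt" & ph2$sensor_id != "pbt1"] <- 35
  expect_equal(bin_physio(ph2)$pbt, rep((34 + 35 + 35) / 3, 45),
               tolerance = 1e-9)

  # constant CBT 36.56 and PBT 34.98 reproduce the regular-mattress
  # nocturnal gradient of 1.58 degC
  b3 <- bin_physio(constant_physio(cbt = 36.56, pbt = 34.98))
  expect_equal(unique(round(b3$gradient, 2)), 1.58)

  # < 50% of expected samples in a bin -> invalid
  ph5 <- constant_physio()
  ph5 <- ph5[!(ph5$variable == "cbt" & ph5$time_s < 330), ]  # 22 of 40 gone
  b5 <- bin_physio(ph5)
  expect_false(b5$valid_cbt[1])
  expect_true(all(b5$valid_cbt[-1]))
  expect_true(is.na(b5$gradient[1]))

  expect_warning(b6 <- bin_physio(constant_physio()[
    constant_physio()$variable != "hr", ]), "no samples")
  expect_true(all(!b6$valid_hr))

  bad <- constant_physio(); bad$time_s[1] <- 27000
  expect_error(bin_physio(bad), "\\[0, 27000\\)")
})

test_that("nocturnal and group summaries follow the stated semantics", {
  bt <- as_bt(cbind(bin_hypnogram(rep("N2", 900)),
                    bin_physio(constant_physio())[-1]))
  ns <- nocturnal_summary(bt)
  cbt <- ns[ns$variable == "cbt", ]
  expect_equal(cbt$sd, 0)
  expect_equal(cbt$min, cbt$mean)
  expect_equal(cbt$max, cbt$mean)
  expect_true(all(ns$min <= ns$mean + 1e-12 & ns$mean <= ns$max + 1e-12))

  two <- list(data.frame(variable = "x", mean = 1.0),
              data.frame(variable = "x", mean = 2.0))
  gs <- group_summary(two)
  expect_equal(gs$mean, 1.5)
  expect_equal(round(gs$sd, 4), 0.7071)

  # group HM-LM difference of condition means: 1.87 - 1.58 = 0.29
  expect_equal(1.87 - 1.58, 0.29, tolerance = 1e-12)
})

test_that("paired_delta is zero on identical nights, antisymmetric, and splits parts at bin 19", {
  hyp <- build_hypnogram(list(c(4L, 2L, 7L, 4L, 3L)))
  mk <- function(cond, physio = constant_physio())
    as_bt(cbind(bin_hypnogram(hyp), bin_physio(physio)[-1]), condition = cond)
  pd0 <- paired_delta(mk("HM"), mk("LM"))
  expect_true(all(abs(unlist(pd0$bins[coolsleep:::ALL_VARS])) < 1e-12))
  expect_true(all(abs(pd0$nightly) < 1e-12))

  hm <- mk("HM", constant_physio(cbt = 36.3))
  lm <- mk("LM", constant_physio(cbt = 36.5))
  pd <- paired_delta(hm, lm)
  # swapping conditions negates every delta (relabel to satisfy the guard)
  hm2 <- lm; attr(hm2, "condition") <- "HM"
  lm2 <- hm; attr(lm2, "condition") <- "LM"
  pd_sw <- paired_delta(hm2, lm2)
  expect_equal(pd_sw$nightly, -pd$nightly)
  expect_equal(pd_sw$part1, -pd$part1)
  expect_equal(pd_sw$part2, -pd$part2)

  # partition: bins 0-18 first part, 19-44 second, exact and disjoint
  expect_equal(sum(pd$bins$bin < 19), 19L)
  expect_equal(sum(pd$bins$bin >= 19), 26L)

  expect_error(paired_delta(mk("HM"), mk("HM")), "HM then the LM")

  # nightly stage delta in min/7.5 h equals 45 x the mean per-bin delta
  d <- default_deltas()[[1]]
  expect_equal(d$nightly[["n3"]] * 45,
               mean(d$bins$n3) * 45, tolerance = 1e-9)
})

test_that("hypnogram and physio CSV round-trip preserves the cohort", {
  spec <- cohort_spec(seed = 3L, study_sizes = c(1L, 1L, 1L))
  co <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  hyps <- read_hypnogram_csv(file.path(dir, "hypnogram.csv"))
  expect_length(hyps, 6L)
  for (s in co) {
    key <- paste(s$hm$subject_id, "HM", sep = "|")
    expect_equal(as.character(hyps[[key]]), s$hm$hypnogram)
  }
  phys <- read_physio_csv(file.path(dir, "physio.csv"))
  key <- paste(co[[1]]$lm$subject_id, "LM", sep = "|")
  expect_equal(phys[[key]]$value, co[[1]]$lm$physio$value, tolerance = 1e-6)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_subjects, 3L)

  # validation errors carry the offending row / value
  bad <- utils::read.csv(file.path(dir, "hypnogram.csv"))
  bad$stage[5] <- "N4"
  f <- file.path(dir, "bad.csv")
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_hypnogram_csv(f), "row 6.*N4")
  bad2 <- utils::read.csv(file.path(dir, "hypnogram.csv"))
  bad2 <- bad2[-3, ]
  utils::write.csv(bad2, f, row.names = FALSE)
  expect_error(read_hypnogram_csv(f), "non-contiguous|missing")
})
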