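# End-to-end orchestration: simulate (or load CSVs) -> bin -> deltas ->
# nocturnal summaries, per-bin + cumulative-sum tests, correlation table,
# spectra + peak period, cycle folding, cosinor, mediation, median split.
# All analysis constants surface as config keys with the study defaults.

#' Default pipeline configuration
#'
#' @param seed Integer seed (drives the simulated cohort and the bootstrap).
#' @param out_dir Output directory.
#' @return Named list of configuration values: \code{input} ("simulate" or
#'   "csv"), \code{hypnogram_csv}/\code{physio_csv} (when \code{input} =
#'   "csv"), \code{cohort} (a [cohort_spec()]), \code{night_part_boundary}
#'   (min), \code{fdr_q}, \code{period_source} ("data-derived" or
#'   "fixed:110"), \code{n_boot}, \code{ci_level}, \code{out_dir}.
#' @export
default_config <- function(seed = 1L, out_dir = "coolsleep_out") {
  list(input = "simulate",
       hypnogram_csv = NULL, physio_csv = NULL,
       cohort = cohort_spec(seed = seed),
       night_part_boundary = 190, fdr_q = 0.05,
       period_source = "data-derived",
       n_boot = 1000L, ci_level = 0.95,
       seed = as.integer(seed), out_dir = out_dir)
}

load_config <- function(path, seed = NULL, out_dir = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config(seed = cfg$seed %||% seed %||% 1L,
                         out_dir = cfg$out_dir %||% out_dir %||% "coolsleep_out")
  if (!is.null(cfg$cohort)) {
    base$cohort <- do.call(cohort_spec,
                           cfg$cohort[names(cfg$cohort) %in% names(formals(cohort_spec))])
  }
  for (k in setdiff(names(cfg), "cohort")) base[[k]] <- cfg[[k]]
  if (!is.null(seed)) {
    base$seed <- as.integer(seed)
    base$cohort$seed <- as.integer(seed)
  }
  if (!is.null(out_dir)) base$out_dir <- out_dir
  base
}

cohort_from_csv <- function(hyp_path, phys_path) {
  hyps <- read_hypnogram_csv(hyp_path)
  phys <- if (!is.null(phys_path)) read_physio_csv(phys_path) else NULL
  ids <- unique(vapply(hyps, attr, "", "subject_id"))
  lapply(ids, function(id) {
    mk <- function(cond) {
      k <- paste(id, cond, sep = "|")
      h <- hyps[[k]]
      if (is.null(h)) stop("missing ", cond, " night for subject ", id)
      structure(list(subject_id = id, study = attr(h, "study"),
                     condition = cond, hypnogram = as.character(h),
                     physio = phys[[k]]),
                class = "night_recording")
    }
    list(profile = list(subject_id = id), hm = mk("HM"), lm = mk("LM"))
  })
}

#' Run the full analysis pipeline
#'
#' Produces the study-shaped outputs under \code{config$out_dir}:
#' \code{table1.csv} (nocturnal group summaries per condition and HM-LM),
#' \code{table2.csv} (night-part correlation matrix), \code{timecourses.csv}
#' (per-bin delta tests and cumulative sums), \code{spectra.csv} +
#' \code{peak.json}, \code{folded_cycles.csv}, \code{cosinor.json},
#' \code{mediation.json}, \code{heterogeneity.json}, and a \code{report.json}
#' aggregating the headline numbers, plus \code{run_log.json}.
#'
#' @param config A [default_config()]-shaped list.
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  cohort <- switch(config$input,
    simulate = generate_cohort(config$cohort),
    csv = cohort_from_csv(config$hypnogram_csv, config$physio_csv),
    stop("config$input must be 'simulate' or 'csv'"))
  binned <- bin_cohort(cohort)
  deltas <- delta_cohort(binned)
  have_physio <- "cbt" %in% names(binned[[1]]$hm)
  q <- config$fdr_q

  # --- nocturnal summary table (per condition and HM-LM) -----------------
  gs_hm <- group_summary(lapply(binned, function(s) nocturnal_summary(s$hm)))
  gs_lm <- group_summary(lapply(binned, function(s) nocturnal_summary(s$lm)))
  d_sum <- lapply(deltas, function(d)
    data.frame(variable = names(d$nightly), mean = unname(d$nightly)))
  gs_d <- group_summary(d_sum)
  tab1 <- rbind(cbind(condition = "LM", gs_lm),
                cbind(condition = "HM", gs_hm),
                cbind(condition = "HM-LM", gs_d))
  utils::write.csv(tab1, out("table1.csv"), row.names = FALSE)

  # --- per-bin and cumulative-sum tests ----------------------------------
  vars <- intersect(ALL_VARS, names(deltas[[1]]$bins))
  tc <- do.call(rbind, lapply(vars, function(v) {
    plain <- per_bin_paired_test(delta_matrix(deltas, v), q = q)
    cs <- cumsum_timecourse(deltas, v, q = q)
    rbind(cbind(variable = v, kind = "delta", plain),
          cbind(variable = v, kind = "cumsum", cs))
  }))
  utils::write.csv(tc, out("timecourses.csv"), row.names = FALSE)

  # --- correlation table + mediation (need physio) ------------------------
  tab2 <- med <- NULL
  if (have_physio) {
    tab2 <- correlation_table(deltas)
    utils::write.csv(tab2, out("table2.csv"), row.names = FALSE)
    X <- vapply(deltas, function(d) d$part2[["cbt"]], 0)
    M <- vapply(deltas, function(d) d$part2[["pbt"]], 0)
    med <- lapply(c(n3 = "n3", rem = "rem", hr = "hr"), function(v) {
      Y <- vapply(deltas, function(d) d$part2[[v]], 0)
      r <- mediate(X, M, Y, n_boot = config$n_boot, seed = config$seed,
                   ci_level = config$ci_level)
      list(outcome = v, a = r$a, b = r$b, c_prime = r$c_prime,
           indirect = r$indirect, total = r$total,
           ci = apply(r$ci, 1, as.list), p = as.list(r$p), n = r$n)
    })
    jsonlite::write_json(med, out("mediation.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  # --- spectra, period, folding, cosinor ---------------------------------
  spec_vars <- c("n2", "n3", "rem")
  spectra <- lapply(spec_vars, function(v) {
    m <- delta_matrix(deltas, v)
    m[is.na(m)] <- 0
    group_spectrum(lapply(seq_len(ncol(m)), function(i) m[-1L, i]))
  })
  names(spectra) <- spec_vars
  sp_df <- do.call(rbind, lapply(spec_vars, function(v)
    cbind(variable = v, spectra[[v]]$spectrum)))
  utils::write.csv(sp_df, out("spectra.csv"), row.names = FALSE)
  peaks <- lapply(spectra, function(s)
    list(frequency = s$peak_frequency, period = s$peak_period, k = s$peak_k))
  jsonlite::write_json(peaks, out("peak.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  period <- if (identical(config$period_source, "data-derived")) {
    cand <- vapply(spectra[c("n3", "rem")], `[[`, 0, "peak_period")
    per <- as.numeric(names(sort(table(cand), decreasing = TRUE))[1])
    if ((FOLD_N * BIN_MIN) %% per != 0) 110 else per   # fall back to default grid
  } else as.numeric(sub("fixed:", "", config$period_source))

  fold_n3 <- fold_cohort(deltas, "n3", period)
  fold_rem <- fold_cohort(deltas, "rem", period)
  fc_df <- rbind(
    data.frame(variable = "n3", t = (seq_len(nrow(fold_n3)) - 0.5) * BIN_MIN,
               mean = rowMeans(fold_n3),
               sem = apply(fold_n3, 1, stats::sd) / sqrt(ncol(fold_n3))),
    data.frame(variable = "rem", t = (seq_len(nrow(fold_rem)) - 0.5) * BIN_MIN,
               mean = rowMeans(fold_rem),
               sem = apply(fold_rem, 1, stats::sd) / sqrt(ncol(fold_rem))))
  utils::write.csv(fc_df, out("folded_cycles.csv"), row.names = FALSE)

  cos_n3 <- population_cosinor(fold_n3, period = period)
  cos_rem <- population_cosinor(fold_rem, period = period)
  pd <- phase_difference(cos_n3$fits, cos_rem$fits, period = period)
  cos_out <- list(
    period = period,
    n3 = list(mesor = cos_n3$mesor, amplitude = cos_n3$amplitude,
              acrophase = cos_n3$acrophase,
              rhythmicity = cos_n3$rhythmicity[c("F", "df1", "df2", "p")]),
    rem = list(mesor = cos_rem$mesor, amplitude = cos_rem$amplitude,
               acrophase = cos_rem$acrophase,
               rhythmicity = cos_rem$rhythmicity[c("F", "df1", "df2", "p")]),
    phase_difference = pd[c("mean", "sd", "t", "df", "p", "d", "n_used")])
  jsonlite::write_json(cos_out, out("cosinor.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  # --- heterogeneity ------------------------------------------------------
  het_out <- NULL
  if (have_physio) {
    het <- median_split_analysis(deltas, q = q, period = period)
    het_out <- list(
      g_test = het$g_test[c("G2", "df", "p")],
      contingency = as.data.frame(het$contingency),
      subgroups = lapply(het$subgroups, function(sg) list(
        n = sg$n,
        n3_sig_bins = sg$n3$folded_test$bin[sg$n3$folded_test$sig],
        rem_sig_bins = sg$rem$folded_test$bin[sg$rem$folded_test$sig],
        n3_acrophase = sg$n3$cosinor$acrophase,
        rem_acrophase = sg$rem$cosinor$acrophase)))
    jsonlite::write_json(het_out, out("heterogeneity.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  # --- headline report ----------------------------------------------------
  n3_nightly <- vapply(deltas, function(d) d$nightly[["n3"]], 0) * N_BINS
  an <- condition_anova(
    vapply(binned, function(s) mean(s$hm$n3), 0),
    vapply(binned, function(s) mean(s$lm$n3), 0),
    vapply(binned, function(s) s$profile$study %||% NA_integer_, NA_integer_))
  report <- list(
    n_subjects = length(deltas),
    delta_n3_min_per_night = mean(n3_nightly),
    delta_n3_sd = stats::sd(n3_nightly),
    delta_n3_d = cohens_d_paired(n3_nightly),
    delta_n3_anova = an[c("F", "df1", "df2", "p", "eta_squared")],
    cycle_period_min = period,
    peak_frequency_per_min = spectra$n3$peak_frequency,
    acrophase_n3 = cos_n3$acrophase,
    acrophase_rem = cos_rem$acrophase,
    phase_difference_min = pd$mean, phase_difference_d = pd$d,
    n3_cumsum_sig_bins = attr(cumsum_timecourse(deltas, "n3", q = q), "sig_bins"),
    settings = list(night_part_boundary = config$night_part_boundary,
                    fdr_q = q, period_source = config$period_source,
                    n_boot = config$n_boot, ci_level = config$ci_level,
                    seed = config$seed))
  if (have_physio) {
    grad <- vapply(deltas, function(d) d$nightly[["gradient"]], 0)
    n3p2 <- vapply(deltas, function(d) d$part2[["n3"]], 0)
    ct <- pearson(grad, n3p2)
    report$gradient_vs_n3_part2 <- ct[c("r", "p", "r_squared", "n")]
    report$mediation_n3 <- med$n3[c("indirect", "c_prime", "p")]
    report$heterogeneity_g_test <- het_out$g_test
  }
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(seed = config$seed, n_subjects = length(deltas),
         package_version = as.character(utils::packageVersion("coolsleep")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         fdr_family = "45 bins per variable (11 for folded subgroups)"),
    out("run_log.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' Command-line entry point
#'
#' Verbs: \code{simulate} (write a synthetic cohort as CSV), \code{analyze}
#' / \code{report} / \code{all} (run the full pipeline). Options:
#' \code{--config FILE} (JSON), \code{--seed N}, \code{--out DIR}.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the result of the verb.
#' @export
coolsleep_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: coolsleep <simulate|analyze|report|all> ",
                          "[--config FILE] [--seed N] [--out DIR]")
  verb <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) && i[1] < length(args)) args[i[1] + 1L] else default
  }
  seed <- as.integer(opt("seed", "1"))
  out_dir <- opt("out", "coolsleep_out")
  cfg_path <- opt("config")
  config <- if (!is.null(cfg_path)) load_config(cfg_path, seed = seed,
                                                out_dir = out_dir)
            else default_config(seed = seed, out_dir = out_dir)
  switch(verb,
    simulate = {
      cohort <- generate_cohort(config$cohort)
      write_cohort(cohort, config$out_dir)
      message("cohort written to ", config$out_dir)
      invisible(config$out_dir)
    },
    analyze = ,
    report = ,
    all = invisible(run_pipeline(config)),
    stop("unknown verb: ", verb))
}
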