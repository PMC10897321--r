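# Per-bin paired testing with Benjamini-Hochberg FDR control, cumulative-sum
# timecourses, the repeated-measures condition test, correlations and effect
# sizes. The FDR family is always the 45 bins of one variable.

#' Per-bin one-sample paired test with FDR control
#'
#' One-sample two-sided t test of mean delta = 0 in each 10-min bin,
#' Benjamini-Hochberg adjusted across the bins of the variable. Bins with
#' fewer than 3 subjects are excluded (NA row).
#'
#' @param mat Bins-by-subjects delta matrix (see [delta_matrix()]).
#' @param q FDR level for the significance flag.
#' @return Data frame per bin: bin, n, mean, sem, t, p, p_adj, sig; the
#'   significant bins as attribute \code{sig_bins}.
#' @export
per_bin_paired_test <- function(mat, q = 0.05) {
  nb <- nrow(mat)
  out <- data.frame(bin = seq_len(nb) - 1L, n = NA_integer_,
                    mean = NA_real_, sem = NA_real_,
                    t = NA_real_, p = NA_real_)
  for (b in seq_len(nb)) {
    x <- mat[b, ]
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 3L) next
    m <- mean(x)
    se <- stats::sd(x) / sqrt(n)
    tt <- if (se > 0) m / se else if (m == 0) 0 else Inf * sign(m)
    out[b, c("n", "mean", "sem", "t", "p")] <-
      list(n, m, se, tt, 2 * stats::pt(-abs(tt), n - 1L))
  }
  tested <- which(is.finite(out$p))
  out$p_adj <- NA_real_
  out$p_adj[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out$sig <- !is.na(out$p_adj) & out$p_adj < q
  attr(out, "sig_bins") <- out$bin[out$sig]
  attr(out, "q") <- q
  out
}

#' Cumulative-sum timecourse test
#'
#' Per subject, the running sum of the per-bin deltas over bins 0..b; then
#' the same per-bin test + BH adjustment as [per_bin_paired_test()]. Used to
#' detect small but systematic condition effects that accumulate over the
#' night.
#'
#' @param deltas List of [paired_delta()] objects.
#' @param var Variable name.
#' @param q FDR level.
#' @return As [per_bin_paired_test()].
#' @export
cumsum_timecourse <- function(deltas, var, q = 0.05) {
  per_bin_paired_test(delta_matrix(deltas, var, cumulative = TRUE), q = q)
}

#' Paired Cohen's d
#'
#' d = mean of the paired differences divided by their SD. Either supply the
#' printed summary statistics or a raw difference vector.
#'
#' @param mean_diff Mean difference, or a numeric vector of differences if
#'   \code{sd_diff} is missing.
#' @param sd_diff SD of the differences (> 0).
#' @return Cohen's d (dimensionless).
#' @examples
#' cohens_d_paired(7.5, 21.6)
#' @export
cohens_d_paired <- function(mean_diff, sd_diff) {
  if (missing(sd_diff)) {
    x <- mean_diff[is.finite(mean_diff)]
    mean_diff <- mean(x)
    sd_diff <- stats::sd(x)
  }
  if (!is.finite(sd_diff) || sd_diff <= 0)
    stop("cohens_d_paired: sd_diff must be positive")
  mean_diff / sd_diff
}

#' Within-subject condition test (repeated-measures ANOVA)
#'
#' Classical repeated-measures decomposition for the two-level within-subject
#' mattress factor; for two conditions the F statistic equals the square of
#' the paired t statistic. The study factor enters as a between-subject
#' stratum (descriptive partition of the subject sum of squares). Effect
#' size eta squared = SS_condition / SS_total.
#'
#' @param hm,lm Per-subject nightly values under each condition.
#' @param study Optional study labels (between-subject stratum).
#' @return List: F, df1, df2, p, eta_squared, t, n, and the SS partition.
#' @export
condition_anova <- function(hm, lm, study = NULL) {
  ok <- is.finite(hm) & is.finite(lm)
  if (any(!ok)) message("condition_anova: excluding ", sum(!ok), " unpaired subject(s)")
  hm <- hm[ok]; lm <- lm[ok]
  if (!is.null(study)) study <- study[ok]
  n <- length(hm)
  if (n < 2L) stop("condition_anova: need at least 2 complete pairs")
  y <- c(hm, lm)
  grand <- mean(y)
  subj_means <- (hm + lm) / 2
  cond_means <- c(mean(hm), mean(lm))
  ss_total <- sum((y - grand)^2)
  ss_subject <- 2 * sum((subj_means - grand)^2)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_error <- ss_total - ss_subject - ss_cond
  df2 <- n - 1L
  f <- if (ss_error <= 0) {
    if (ss_cond == 0) 0 else Inf
  } else (ss_cond / 1) / (ss_error / df2)
  d <- hm - lm
  tt <- if (stats::sd(d) > 0) mean(d) / (stats::sd(d) / sqrt(n)) else 0
  ss_study <- NA_real_
  if (!is.null(study) && length(unique(study)) > 1L) {
    sm <- tapply(subj_means, study, mean)
    ns <- tapply(subj_means, study, length)
    ss_study <- 2 * sum(ns * (sm - grand)^2)
  }
  list(F = f, df1 = 1L, df2 = df2,
       p = if (is.finite(f)) f_upper_p(f, 1, df2) else 0,
       eta_squared = if (ss_total > 0) ss_cond / ss_total else 0,
       t = tt, n = n,
       ss = c(condition = ss_cond, subject = ss_subject,
              study = ss_study, error = ss_error, total = ss_total))
}

#' Pearson correlation with coefficient of determination
#'
#' p from t = r sqrt(n-2) / sqrt(1-r^2) with n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors (pairwise-complete, n >= 3 after removal).
#' @return List: r, r_squared, p, n.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("pearson: need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson: zero variance in x or y")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(r = r, r_squared = r^2, p = p, n = n)
}

#' Night-part correlation table of temperature vs sleep-stage effects
#'
#' Correlates each temperature/heart-rate delta (nightly means of delta-CBT,
#' delta-PBT, delta-CBT-PBT, delta-HR) with the stage deltas (delta-N3,
#' delta-REM night-part means), separately for the first ([0, 190) min) and
#' second ([190, 450) min) part of the night.
#'
#' @param deltas List of [paired_delta()] objects.
#' @param temp_vars,stage_vars Variables to cross.
#' @return Tidy data frame: temp_var, stage_var, part, n, r, p, r_squared.
#' @export
correlation_table <- function(deltas,
                              temp_vars = c("cbt", "pbt", "gradient", "hr"),
                              stage_vars = c("n3", "rem")) {
  rows <- list()
  for (tv in temp_vars) {
    tvals <- vapply(deltas, function(d) d$nightly[[tv]], 0)
    for (sv in stage_vars) for (part in c("part1", "part2")) {
      svals <- vapply(deltas, function(d) d[[part]][[sv]], 0)
      ct <- pearson(tvals, svals)
      rows[[length(rows) + 1L]] <- data.frame(
        temp_var = tv, stage_var = sv,
        part = if (part == "part1") "0-190" else "190-450",
        n = ct$n, r = ct$r, p = ct$p, r_squared = ct$r_squared)
    }
  }
  do.call(rbind, rows)
}
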