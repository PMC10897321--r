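# Heterogeneity of the treatment effect: median split by the nightly
# CBT-PBT gradient delta, and the likelihood-ratio (G) test of study
# balance across the split.

#' Median split of per-subject values
#'
#' Values below the sample median are labelled "small", values at or above
#' it "large" (the tie rule; with continuous data and even n the groups are
#' equal). Subjects with undefined values get NA labels.
#'
#' @param values Per-subject split values (e.g. nightly delta CBT-PBT).
#' @return Factor with levels small/large, same length as \code{values}.
#' @export
median_split <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2L) stop("median_split: need at least 2 defined values")
  if (length(unique(values[ok])) == 1L)
    stop("median_split: all values identical, split undefined")
  med <- stats::median(values[ok])
  lab <- rep(NA_character_, length(values))
  lab[ok] <- ifelse(values[ok] < med, "small", "large")
  factor(lab, levels = c("small", "large"))
}

#' Likelihood-ratio (G) test of independence
#'
#' G^2 = 2 sum O log(O / E) over the cells of an r x c contingency table,
#' expected counts from the row/column margins; df = (r-1)(c-1); p from the
#' upper chi-square tail. Zero observed cells contribute 0; zero margins are
#' an error.
#'
#' @param tab Matrix or table of counts.
#' @return List: G2, df, p, expected.
#' @export
g_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("g_test: negative counts")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("g_test: zero row or column margin")
  E <- outer(rs, cs) / sum(tab)
  terms <- ifelse(tab > 0, tab * log(tab / E), 0)
  G2 <- 2 * sum(terms)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(G2 = G2, df = df, p = chi2_upper_p(max(0, G2), df), expected = E)
}

#' Median-split heterogeneity analysis of a delta cohort
#'
#' Splits the cohort by the nightly delta CBT-PBT, tests study balance
#' across the split with [g_test()], and reruns the folded-cycle per-bin
#' analysis (11-bin FDR family) and population cosinor for delta-N3 and
#' delta-REM within each subgroup.
#'
#' @param deltas List of [paired_delta()] objects.
#' @param q FDR level for the subgroup folded-cycle post-hocs.
#' @param period Cycle period in minutes.
#' @return List: labels, g_test, contingency, subgroups (per label: n,
#'   per-variable folded test + cosinor).
#' @export
median_split_analysis <- function(deltas, q = 0.05, period = 110) {
  grad <- vapply(deltas, function(d) d$nightly[["gradient"]], 0)
  study <- vapply(deltas, function(d) d$study, 0L)
  labels <- median_split(grad)
  ok <- !is.na(labels)
  tab <- table(study = study[ok], split = labels[ok])
  gt <- g_test(tab)
  subgroups <- lapply(levels(labels), function(lv) {
    sub <- deltas[ok & labels == lv]
    res <- lapply(c(n3 = "n3", rem = "rem"), function(v) {
      fm <- fold_cohort(sub, v, period)
      list(folded_test = per_bin_paired_test(fm, q = q),
           cosinor = population_cosinor(fm, period = period))
    })
    c(list(n = length(sub)), res)
  })
  names(subgroups) <- levels(labels)
  list(labels = labels, split_values = grad, g_test = gt,
       contingency = tab, subgroups = subgroups)
}
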