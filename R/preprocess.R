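# Aggregation to the 45 x 10-min analysis grid and paired HM-LM deltas.
# Bins are 0-based half-open: bin b covers minutes [10b, 10(b+1)).

#' Aggregate a hypnogram to stage minutes per 10-min bin
#'
#' Wake and N1 are pooled (the light/wake composite); each 30-s epoch
#' contributes 0.5 min, so every bin's stage minutes sum to exactly 10.
#'
#' @param stages Character vector of 900 epoch labels (W/N1/N2/N3/REM).
#' @return Data frame with 45 rows: bin, wn1, n2, n3, rem (min/10 min).
#' @export
bin_hypnogram <- function(stages) {
  if (length(stages) != 900L)
    stop("hypnogram must have exactly 900 epochs of 30 s (got ",
         length(stages), ")")
  if (any(!stages %in% STAGES))
    stop("unknown stage label: ", stages[which(!stages %in% STAGES)][1])
  bin <- rep(seq_len(N_BINS) - 1L, each = 20L)
  pooled <- ifelse(stages %in% c("W", "N1"), "WN1", stages)
  counts <- table(factor(bin, levels = 0:(N_BINS - 1L)),
                  factor(pooled, levels = c("WN1", "N2", "N3", "REM")))
  out <- as.data.frame.matrix(counts * 0.5)
  names(out) <- STAGE_VARS
  data.frame(bin = 0:(N_BINS - 1L), out, row.names = NULL)
}

#' Aggregate physiological series to per-bin means
#'
#' Sensor channels (3 PBT, 5 MAT) are pooled with equal weight within each
#' bin. A bin with fewer than half its expected samples is flagged invalid.
#' The conductive gradient is CBT minus PBT per bin.
#'
#' @param physio Data frame with columns variable, sensor_id, time_s, value.
#' @return Data frame with 45 rows: bin, cbt, pbt, mat, hr, gradient and
#'   logical validity flags valid_cbt, valid_pbt, valid_mat, valid_hr,
#'   valid_gradient.
#' @export
bin_physio <- function(physio) {
  if (any(physio$time_s < 0 | physio$time_s >= NIGHT_MIN * 60))
    stop("sample times must lie in [0, ", NIGHT_MIN * 60, ") s")
  expected <- c(cbt = 40, pbt = 30, mat = 50, hr = 600)  # samples per bin
  out <- data.frame(bin = 0:(N_BINS - 1L))
  for (v in PHYSIO_VARS) {
    sub <- physio[physio$variable == v, ]
    if (!nrow(sub)) {
      warning("no samples for variable '", v, "'; all bins invalid")
      out[[v]] <- NA_real_
      out[[paste0("valid_", v)]] <- FALSE
      next
    }
    b <- factor(floor(sub$time_s / 600), levels = 0:(N_BINS - 1L))
    m <- tapply(sub$value, b, mean)
    n <- tapply(sub$value, b, length)
    n[is.na(n)] <- 0
    valid <- n >= expected[[v]] / 2
    m[!valid] <- NA_real_
    out[[v]] <- as.numeric(m)
    out[[paste0("valid_", v)]] <- as.logical(valid)
  }
  out$gradient <- out$cbt - out$pbt
  out$valid_gradient <- out$valid_cbt & out$valid_pbt
  out
}

#' Bin one night recording
#'
#' @param recording A [night_recording] (hypnogram plus physio).
#' @return A \code{binned_timecourse}: 45-row data frame of stage minutes,
#'   physio means, gradient and validity flags, with subject metadata in
#'   attributes.
#' @export
bin_night <- function(recording) {
  hyp <- bin_hypnogram(recording$hypnogram)
  out <- if (!is.null(recording$physio)) {
    phys <- bin_physio(recording$physio)
    merge(hyp, phys, by = "bin", sort = TRUE)
  } else hyp
  structure(out, class = c("binned_timecourse", "data.frame"),
            subject_id = recording$subject_id, study = recording$study,
            condition = recording$condition)
}

#' Bin a whole cohort
#'
#' @param cohort A [generate_cohort()] result (or equivalent list).
#' @return List per subject with elements profile, hm, lm (binned).
#' @export
bin_cohort <- function(cohort) {
  lapply(cohort, function(s)
    list(profile = s$profile, hm = bin_night(s$hm), lm = bin_night(s$lm)))
}

#' Nocturnal summary of one binned night
#'
#' Subject-level mean, SD, min and max over the valid bins, per variable.
#'
#' @param bt A [bin_night()] result.
#' @return Data frame: variable, mean, sd, min, max, n_bins.
#' @export
nocturnal_summary <- function(bt) {
  vars <- intersect(ALL_VARS, names(bt))
  rows <- lapply(vars, function(v) {
    x <- bt[[v]]
    vf <- bt[[paste0("valid_", v)]]
    if (!is.null(vf)) x <- x[vf]
    x <- x[is.finite(x)]
    if (!length(x))
      return(data.frame(variable = v, mean = NA_real_, sd = NA_real_,
                        min = NA_real_, max = NA_real_, n_bins = 0L))
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x), n_bins = length(x))
  })
  do.call(rbind, rows)
}

#' Group-level summary across subjects
#'
#' Mean, SD, min and max across the subjects' nocturnal means (the group
#' semantics of a per-condition summary table); N reflects per-variable
#' missingness.
#'
#' @param summaries List of [nocturnal_summary()] data frames.
#' @return Data frame: variable, n, mean, sd, min, max.
#' @export
group_summary <- function(summaries) {
  vars <- unique(unlist(lapply(summaries, function(s) s$variable)))
  rows <- lapply(vars, function(v) {
    m <- vapply(summaries, function(s) {
      i <- match(v, s$variable)
      if (is.na(i)) NA_real_ else s$mean[i]
    }, 0)
    m <- m[is.finite(m)]
    data.frame(variable = v, n = length(m), mean = mean(m),
               sd = stats::sd(m), min = min(m), max = max(m))
  })
  do.call(rbind, rows)
}

#' Paired HM-LM delta timecourses and summaries for one subject
#'
#' Per-bin deltas are computed only on bins valid in both nights; nightly
#' deltas are differences of nocturnal means taken over the jointly valid
#' bins (so swapping the arguments negates every delta). Night-part means
#' split the night at 190 min, the boundary bin belonging to the second
#' part: first = bins 0-18 ([0, 190) min), second = bins 19-44
#' ([190, 450) min).
#'
#' @param hm,lm Binned timecourses of the same subject, conditions HM and LM.
#' @return A \code{paired_delta}: list with \code{bins} (per-bin deltas +
#'   validity), \code{nightly}, \code{part1}, \code{part2} (named numeric
#'   vectors over variables), and subject metadata.
#' @export
paired_delta <- function(hm, lm) {
  if (!identical(attr(hm, "subject_id"), attr(lm, "subject_id")))
    stop("paired_delta: recordings belong to different subjects")
  if (!identical(attr(hm, "condition"), "HM") ||
      !identical(attr(lm, "condition"), "LM"))
    stop("paired_delta: arguments must be the HM then the LM night")
  vars <- intersect(ALL_VARS, intersect(names(hm), names(lm)))
  bins <- data.frame(bin = hm$bin)
  first <- bins$bin < 19L            # minutes [0, 190)
  nightly <- part1 <- part2 <- stats::setNames(rep(NA_real_, length(vars)), vars)
  for (v in vars) {
    vf_h <- hm[[paste0("valid_", v)]] %||% rep(TRUE, N_BINS)
    vf_l <- lm[[paste0("valid_", v)]] %||% rep(TRUE, N_BINS)
    ok <- vf_h & vf_l
    d <- hm[[v]] - lm[[v]]
    d[!ok] <- NA_real_
    bins[[v]] <- d
    bins[[paste0("valid_", v)]] <- ok
    if (any(ok)) {
      nightly[v] <- mean(hm[[v]][ok]) - mean(lm[[v]][ok])
      if (any(ok & first)) part1[v] <- mean(d[ok & first])
      if (any(ok & !first)) part2[v] <- mean(d[ok & !first])
    }
  }
  structure(list(subject_id = attr(hm, "subject_id"),
                 study = attr(hm, "study"),
                 bins = bins, nightly = nightly,
                 part1 = part1, part2 = part2),
            class = "paired_delta")
}

#' Paired deltas for a whole binned cohort
#'
#' @param binned A [bin_cohort()] result.
#' @return List of [paired_delta()] objects.
#' @export
delta_cohort <- function(binned) {
  lapply(binned, function(s) paired_delta(s$hm, s$lm))
}

#' Extract a bins-by-subjects delta matrix
#'
#' @param deltas List of [paired_delta()] objects.
#' @param var Variable name (e.g. "n3", "gradient").
#' @param cumulative If TRUE, return per-subject running sums over bins
#'   (missing bins contribute 0).
#' @return 45 x n numeric matrix, one column per subject.
#' @export
delta_matrix <- function(deltas, var, cumulative = FALSE) {
  m <- vapply(deltas, function(d) d$bins[[var]], numeric(N_BINS))
  if (cumulative) {
    m0 <- m
    m0[is.na(m0)] <- 0
    m <- apply(m0, 2L, cumsum)
  }
  colnames(m) <- vapply(deltas, function(d) d$subject_id, "")
  m
}
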