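# Data-derived NREM-REM cycle period estimation: detrended periodogram over
# the 44 usable bins (the first 10 min after lights-off are omitted), and
# folding of timecourses over four 110-min cycles.

FOLD_N <- 44L    # bins 1..44 of the 45-bin grid

#' Detrended periodogram of a nightly timecourse
#'
#' Subtracts the least-squares line, applies the discrete Fourier transform
#' and reports squared amplitude per positive frequency k/(44 * 10) min^-1,
#' k = 1..22. Power is normalised as (|X_k| / (n/2))^2 so a unit-amplitude
#' on-grid cosine yields peak power 1 (units (min/10 min)^2 for stage
#' timecourses).
#'
#' @param x Numeric vector of the 44 bins (bins 1..44; bin 0 omitted).
#' @return Data frame: k, frequency (min^-1), period (min), power.
#' @export
periodogram <- function(x) {
  n <- FOLD_N
  if (length(x) != n || any(!is.finite(x)))
    stop("periodogram: need exactly ", n, " finite values")
  i <- seq_len(n)
  x <- stats::residuals(stats::lm(x ~ i))      # linear detrend
  X <- stats::fft(x)
  k <- seq_len(n %/% 2L)
  freq <- k / (n * BIN_MIN)
  data.frame(k = k, frequency = freq, period = 1 / freq,
             power = (Mod(X[k + 1L]) / (n / 2))^2)
}

#' Group-mean spectrum and peak period
#'
#' Pointwise mean and SEM over per-subject spectra; the peak is the frequency
#' of maximal mean power, searched over periods no longer than half the
#' night (k >= 2 on the 44-bin grid), ties broken toward the lower frequency.
#'
#' @param spectra List of [periodogram()] data frames (or a list of 44-bin
#'   timecourses, which are transformed first).
#' @return List: spectrum (data frame k, frequency, period, power, sem),
#'   peak_k, peak_frequency (min^-1), peak_period (min), n.
#' @export
group_spectrum <- function(spectra) {
  if (!length(spectra)) stop("group_spectrum: need at least one spectrum")
  if (is.numeric(spectra[[1]])) spectra <- lapply(spectra, periodogram)
  pw <- vapply(spectra, function(s) s$power, numeric(nrow(spectra[[1]])))
  m <- rowMeans(pw)
  sem <- apply(pw, 1L, stats::sd) / sqrt(ncol(pw))
  sp <- spectra[[1]][, c("k", "frequency", "period")]
  sp$power <- m
  sp$sem <- sem
  search <- which(sp$period <= NIGHT_MIN / 2)   # k >= 2 (period <= 220 min)
  peak <- search[which.max(m[search])]          # which.max: first max = lower k
  list(spectrum = sp, peak_k = sp$k[peak],
       peak_frequency = sp$frequency[peak], peak_period = sp$period[peak],
       n = ncol(pw))
}

#' Fold a nightly timecourse over sleep cycles
#'
#' Bins 1..44 (minutes 10-450) are reshaped as 4 consecutive cycles of 11
#' bins each (period 110 min) and averaged positionally; the folding origin
#' is minute 10 after lights-off for every subject (no per-subject
#' alignment).
#'
#' @param x Numeric vector of all 45 bins (bin 0 is dropped) or of the 44
#'   usable bins.
#' @param period Cycle period in minutes; \code{period * 4} must equal the
#'   440-min folding window.
#' @return List of class \code{folded_cycle}: cycles (11 x 4 matrix, one
#'   column per cycle), cycle_avg (length 11), t (within-cycle bin midpoints,
#'   min), period.
#' @export
fold_cycles <- function(x, period = 110) {
  if (length(x) == N_BINS) x <- x[-1L]
  if (length(x) != FOLD_N)
    stop("fold_cycles: need 44 usable bins (45 with bin 0)")
  bins_per_cycle <- period / BIN_MIN
  if (bins_per_cycle != round(bins_per_cycle) ||
      FOLD_N %% bins_per_cycle != 0)
    stop("fold_cycles: period ", period,
         " min does not divide the 440-min folding window")
  m <- matrix(x, nrow = bins_per_cycle)
  structure(list(cycles = m, cycle_avg = rowMeans(m),
                 t = (seq_len(bins_per_cycle) - 0.5) * BIN_MIN,
                 period = period),
            class = "folded_cycle")
}

#' Folded-cycle matrix for a cohort
#'
#' @param deltas List of [paired_delta()] objects (or any list whose
#'   elements expose \code{bins[[var]]}).
#' @param var Variable name.
#' @param period Cycle period (minutes).
#' @return 11 x n matrix of per-subject cycle-average timecourses.
#' @export
fold_cohort <- function(deltas, var, period = 110) {
  m <- vapply(deltas, function(d) {
    x <- d$bins[[var]]
    x[is.na(x)] <- 0
    fold_cycles(x, period)$cycle_avg
  }, numeric(period / BIN_MIN))
  colnames(m) <- vapply(deltas, function(d) d$subject_id, "")
  m
}
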