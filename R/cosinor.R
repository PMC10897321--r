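# Cosinor rhythmometry at the fixed 110-min cycle period: per-subject
# least-squares fits, population-mean inference with the zero-amplitude
# (Hotelling-type) rhythmicity test, and circular acrophase differences.

#' Fit a single-component cosinor
#'
#' Least-squares fit of y = M + beta cos(wt) + gamma sin(wt), w = 2 pi /
#' period. Amplitude = sqrt(beta^2 + gamma^2); acrophase (time of the fitted
#' maximum) = (period / 2 pi) atan2(gamma, beta) mod period. A fit on a pure
#' on-grid cosine is exact. The acrophase is flagged undefined when the
#' amplitude is below 1e-6 of the series SD (or the series is constant).
#'
#' @param y Response values.
#' @param t Time points (minutes); default the 11 folded-cycle bin midpoints.
#' @param period Fixed period in minutes.
#' @return List of class \code{cosinor_fit}: mesor, beta, gamma, amplitude,
#'   acrophase (NA if undefined), acrophase_defined, period, fitted,
#'   residuals, n.
#' @export
fit_cosinor <- function(y, t = (seq_along(y) - 0.5) * 10, period = 110) {
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  if (length(y) < 3L) stop("fit_cosinor: need at least 3 time points")
  if (diff(range(t)) < period * (1 - 1 / length(t)) && length(unique(t)) < 3L)
    stop("fit_cosinor: singular design")
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t), sin(w * t))
  qrX <- qr(X)
  if (qrX$rank < 3L) stop("fit_cosinor: singular design")
  coef <- qr.coef(qrX, y)
  mesor <- coef[1]; beta <- coef[2]; gamma <- coef[3]
  amp <- sqrt(beta^2 + gamma^2)
  ysd <- stats::sd(y)
  defined <- is.finite(amp) && ysd > 0 && amp > 1e-6 * ysd
  acro <- if (defined) {
    a <- (period / (2 * pi)) * atan2(gamma, beta) %% (2 * pi)
    if (period - a < 1e-9) 0 else a       # guard the wrap boundary
  } else NA_real_
  fitted <- as.numeric(X %*% coef)
  structure(list(mesor = unname(mesor), beta = unname(beta),
                 gamma = unname(gamma), amplitude = unname(amp),
                 acrophase = unname(acro), acrophase_defined = defined,
                 period = period, fitted = fitted, residuals = y - fitted,
                 n = length(y)),
            class = "cosinor_fit")
}

#' Population-mean cosinor
#'
#' Per-subject fits are averaged on the coefficient scale (mesor, beta,
#' gamma); the population amplitude and acrophase derive from the mean
#' coefficient vector, and rhythmicity is tested with [rhythmicity_test()].
#'
#' @param mat Timepoints-by-subjects matrix (e.g. from [fold_cohort()]).
#' @param t Time points (minutes).
#' @param period Fixed period (minutes).
#' @return List: fits (per subject), mesor, beta, gamma, amplitude,
#'   acrophase, rhythmicity (statistic/df/p), n.
#' @export
population_cosinor <- function(mat, t = (seq_len(nrow(mat)) - 0.5) * 10,
                               period = 110) {
  fits <- apply(mat, 2L, fit_cosinor, t = t, period = period,
                simplify = FALSE)
  B <- cbind(beta = vapply(fits, `[[`, 0, "beta"),
             gamma = vapply(fits, `[[`, 0, "gamma"))
  mb <- colMeans(B)
  amp <- sqrt(sum(mb^2))
  acro <- (period / (2 * pi)) * atan2(mb["gamma"], mb["beta"]) %% (2 * pi)
  if (period - acro < 1e-9) acro <- 0
  rhythm <- rhythmicity_test(B)
  list(fits = fits, mesor = mean(vapply(fits, `[[`, 0, "mesor")),
       beta = unname(mb["beta"]), gamma = unname(mb["gamma"]),
       amplitude = amp, acrophase = unname(acro),
       rhythmicity = rhythm, n = ncol(mat))
}

#' Zero-amplitude rhythmicity test
#'
#' Hotelling-type T-squared test of the bivariate mean of the per-subject
#' (beta, gamma) coefficient pairs against (0, 0):
#' F = ((n - 2) / (2 (n - 1))) T^2 with (2, n - 2) degrees of freedom.
#' Degenerate input (constant coefficients across subjects) gives the
#' contract p = 1 at zero mean and an error otherwise.
#'
#' @param B n x 2 matrix of per-subject (beta, gamma).
#' @return List: T2, F, df1, df2, p, n.
#' @export
rhythmicity_test <- function(B) {
  B <- as.matrix(B)
  n <- nrow(B)
  if (n < 3L) stop("rhythmicity_test: need at least 3 subjects")
  m <- colMeans(B)
  S <- stats::cov(B)
  if (!is.finite(determinant(S, logarithm = FALSE)$modulus) ||
      abs(det(S)) < .Machine$double.eps^2) {
    if (all(abs(m) < .Machine$double.eps^0.5))
      return(list(T2 = 0, F = 0, df1 = 2L, df2 = n - 2L, p = 1, n = n))
    stop("rhythmicity_test: degenerate coefficient covariance")
  }
  T2 <- n * drop(t(m) %*% solve(S, m))
  F <- (n - 2) / (2 * (n - 1)) * T2
  list(T2 = T2, F = F, df1 = 2L, df2 = n - 2L,
       p = f_upper_p(F, 2, n - 2), n = n)
}

#' Circular acrophase difference between two cosinor populations
#'
#' Per-subject differences acrophase(B) - acrophase(A), wrapped to
#' (-period/2, +period/2]; subjects with an undefined acrophase in either
#' fit are excluded pairwise. Summarised by mean, SD, a two-sided paired t
#' test against 0 and Cohen's d.
#'
#' @param fits_a,fits_b Per-subject [fit_cosinor()] lists on the same
#'   subjects (e.g. the \code{fits} element of [population_cosinor()]).
#' @param period Period in minutes.
#' @return List: differences, mean, sd, t, df, p, d, n_used, n_excluded.
#' @export
phase_difference <- function(fits_a, fits_b, period = 110) {
  if (length(fits_a) != length(fits_b))
    stop("phase_difference: fits must cover the same subjects")
  aa <- vapply(fits_a, `[[`, 0, "acrophase")
  ab <- vapply(fits_b, `[[`, 0, "acrophase")
  ok <- is.finite(aa) & is.finite(ab)
  if (sum(ok) < 3L) stop("phase_difference: fewer than 3 usable subjects")
  d <- wrap_phase(ab[ok] - aa[ok], period)
  m <- mean(d); s <- stats::sd(d)
  tt <- if (s > 0) m / (s / sqrt(length(d))) else if (m == 0) 0 else Inf * sign(m)
  list(differences = d, mean = m, sd = s, t = tt, df = length(d) - 1L,
       p = 2 * stats::pt(-abs(tt), length(d) - 1L),
       d = if (s > 0) m / s else 0,
       n_used = length(d), n_excluded = sum(!ok))
}
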