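# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Upper-tail p-value of the F distribution
#'
#' @param f Observed F statistic (must be >= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return Upper-tail probability P(F >= f).
#' @examples
#' f_upper_p(10.638, 1, 71)
#' @export
f_upper_p <- function(f, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) stop("degrees of freedom must be >= 1")
  if (any(f < 0)) stop("F statistic must be non-negative")
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Upper-tail p-value of the chi-square distribution
#'
#' @param x Observed statistic (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return Upper-tail probability P(X2 >= x).
#' @examples
#' chi2_upper_p(4.341, 2)
#' @export
chi2_upper_p <- function(x, df) {
  if (any(df < 1)) stop("degrees of freedom must be >= 1")
  if (any(x < 0)) stop("statistic must be non-negative")
  stats::pchisq(x, df, lower.tail = FALSE)
}

# Row-wise softmax of a score matrix; guards against overflow.
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# Deterministic substream seed: one named stream per (subject, component)
# so that changing one generator parameter does not scramble unrelated draws.
# Kept below 2^31 - 1.
substream_seed <- function(seed, subject_index, component) {
  ((as.numeric(seed) %% 2147483629) * 1000003 +
     subject_index * 131 + component) %% 2147483629
}

# Wrap a phase difference (minutes) into (-period/2, +period/2].
wrap_phase <- function(x, period = 110) {
  period / 2 - ((period / 2 - x) %% period)
}

# Canonical variable sets used throughout.
PHYSIO_VARS <- c("cbt", "pbt", "mat", "hr")
STAGE_VARS  <- c("wn1", "n2", "n3", "rem")
ALL_VARS    <- c(PHYSIO_VARS, "gradient", STAGE_VARS)
N_BINS      <- 45L
BIN_MIN     <- 10
NIGHT_MIN   <- 450
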