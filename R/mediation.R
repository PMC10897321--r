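# Single-mediator linear mediation with nonparametric bootstrap CIs:
# X -> M -> Y with a direct path X -> Y. OLS fits M = a0 + a X and
# Y = c0 + c' X + b M; indirect effect (ACME) = a b, direct (ADE) = c',
# total = c' + a b.

ols_paths <- function(X, M, Y) {
  a <- stats::cov(X, M) / stats::var(X)
  Z <- cbind(1, X, M)
  cf <- qr.coef(qr(Z), Y)
  c(a = unname(a), b = unname(cf[3]), c_prime = unname(cf[2]))
}

#' Single-mediator causal mediation with bootstrap confidence intervals
#'
#' Percentile bootstrap (subjects resampled with replacement) for the
#' indirect (ACME), direct (ADE) and total effects; two-sided bootstrap
#' p values as 2 min(P(est <= 0), P(est >= 0)) over resamples. Deterministic
#' given \code{seed}.
#'
#' @param X,M,Y Per-subject exposure, mediator and outcome values.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param ci_level Confidence level for the percentile intervals.
#' @return List of class \code{mediation_result}: a, b, c_prime, indirect,
#'   total, ci (matrix), p (named), n, n_boot, seed, ci_level.
#' @export
mediate <- function(X, M, Y, n_boot = 1000L, seed = 1L, ci_level = 0.95) {
  ok <- is.finite(X) & is.finite(M) & is.finite(Y)
  X <- X[ok]; M <- M[ok]; Y <- Y[ok]
  n <- length(X)
  if (n < 10L) stop("mediate: need at least 10 complete triples")
  if (abs(stats::cor(X, M)) > 0.999)
    stop("mediate: X and M are collinear (|cor| > 0.999)")
  est <- ols_paths(X, M, Y)
  indirect <- est[["a"]] * est[["b"]]
  total <- est[["c_prime"]] + indirect

  set.seed(as.integer(seed %% 2147483629))
  boot <- matrix(NA_real_, n_boot, 3L,
                 dimnames = list(NULL, c("indirect", "direct", "total")))
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(X[idx]) == 0 || stats::sd(M[idx]) == 0 ||
        abs(stats::cor(X[idx], M[idx])) > 0.999) {
      boot[i, ] <- c(indirect, est[["c_prime"]], total)  # degenerate resample
      next
    }
    e <- ols_paths(X[idx], M[idx], Y[idx])
    ind <- e[["a"]] * e[["b"]]
    boot[i, ] <- c(ind, e[["c_prime"]], e[["c_prime"]] + ind)
  }
  alpha <- (1 - ci_level) / 2
  ci <- t(apply(boot, 2L, stats::quantile, probs = c(alpha, 1 - alpha)))
  pboot <- apply(boot, 2L, function(z)
    min(1, 2 * min(mean(z <= 0), mean(z >= 0))))
  structure(list(a = est[["a"]], b = est[["b"]], c_prime = est[["c_prime"]],
                 indirect = indirect, total = total,
                 ci = ci, p = pboot, n = n, n_boot = n_boot,
                 seed = seed, ci_level = ci_level),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation> n=%d  a=%.4g  b=%.4g  c'=%.4g\n", x$n, x$a, x$b,
              x$c_prime))
  cat(sprintf("  ACME=%.4g [%0.4g, %0.4g] p=%.4g\n", x$indirect,
              x$ci["indirect", 1], x$ci["indirect", 2], x$p[["indirect"]]))
  cat(sprintf("  ADE =%.4g [%0.4g, %0.4g] p=%.4g\n", x$c_prime,
              x$ci["direct", 1], x$ci["direct", 2], x$p[["direct"]]))
  cat(sprintf("  total=%.4g\n", x$total))
  invisible(x)
}
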