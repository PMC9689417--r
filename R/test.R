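#' Weighted CUSUM change-point test
#'
#' Tests for a single change in mean using the studentized WC statistic
#' \deqn{T = \frac{S_n(\bar Y_\bullet;\, \tau,\, 2)}
#'       {(n-1)^{-1} \sum_i (\bar Y_{i\bullet} - \hat\mu_{1,n})^2},}
#' where \eqn{\bar Y_{i\bullet}} are row means of the n x q data matrix
#' (q = 1 for a plain series).  Calibration uses the *exact* finite-n null
#' spectrum from [wc_spectrum()] (a weighted chi-squared sum, evaluated by
#' Imhof's method), not the limit distribution: exact critical values cost
#' the same and converge to the limit anyway.  When the variance of the row
#' means is known it can be supplied via `sigma2`, reproducing the
#' known-variance setting in which the null distribution is exact rather
#' than asymptotic.
#'
#' @param y numeric vector (a series) or n x q matrix (rows = time points,
#'   columns = replicates/dimensions); n >= 3.
#' @param tau weight kind encoding the prior change position: `"right"`
#'   favours early changes, `"center"` central ones, `"left"` late ones;
#'   see [weight_scheme()].
#' @param level test level in (0, 1); default 0.05.
#' @param sigma2 optional known variance of the row-mean series; default
#'   `NULL` uses the plug-in estimator [wc_variance()].
#' @return Object of class `"wc_test"`: list with `statistic` (studentized
#'   value), `sigma2`, `p.value`, `critical.value`, `level`, `k.hat`, `n`,
#'   `q`, `tau`, `gamma`, `variant`, `reject`.
#' @examples
#' set.seed(1)
#' y <- c(rnorm(20), rnorm(20, 2))
#' wc_test(y, "center")
#' @export
wc_test <- function(y, tau = c("center", "left", "right"), level = 0.05,
                    sigma2 = NULL) {
  tau <- match.arg(tau)
  check_level(level)
  x <- row_mean_series(y)
  n <- length(x)
  q <- if (is.matrix(y) || is.data.frame(y)) ncol(y) else 1L
  if (n < 3) stop_invalid("need at least 3 time points")
  scheme <- weight_scheme(n, tau)
  s2 <- if (is.null(sigma2)) wc_variance(x) else {
    if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0)
      stop_invalid("'sigma2' must be a positive scalar")
    sigma2
  }
  S <- wc_statistic(x, scheme)
  T <- S / s2
  sp <- wc_spectrum(n, tau)
  res <- list(statistic = T, sigma2 = s2,
              p.value = wc_pvalue(T, sp),
              critical.value = wc_critical_value(1 - level, sp),
              level = level,
              k.hat = as.integer(estimate_changepoint(x, scheme)),
              n = n, q = q, tau = tau, gamma = 2, variant = "wc")
  res$reject <- res$statistic > res$critical.value
  structure(res, class = "wc_test")
}

#' WC test for Poisson mixed-model counts
#'
#' For counts with a shared per-time latent effect
#' (\eqn{Y_{ij} \mid U_i \sim} Poisson with mean \eqn{e^{\rho_i + U_i}},
#' \eqn{U_i \sim N(0, \nu^2)}), a saddle-point approximation of the marginal
#' likelihood reduces the likelihood-ratio change test to the WC statistic
#' applied to the *log row means* \eqn{\log \bar Y_{i\bullet}} (see
#' [saddlepoint_integral()] for the underlying approximation).  This
#' function applies [wc_test()] to that transformed series; the null
#' spectrum is unchanged.
#'
#' @param counts n x q matrix (or vector) of nonnegative counts; every row
#'   mean must be strictly positive (no automatic continuity correction is
#'   applied — zero rows raise an error naming them).
#' @inheritParams wc_test
#' @return A `"wc_test"` with `variant = "poisson"`.
#' @export
poisson_wc_test <- function(counts, tau = c("center", "left", "right"),
                            level = 0.05) {
  tau <- match.arg(tau)
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m)))
    stop_invalid("'counts' must contain nonnegative integers")
  x <- rowMeans(m)
  bad <- which(x <= 0)
  if (length(bad))
    stop_invalid(sprintf(
      "zero row mean at time point(s) %s: log transform undefined",
      paste(bad, collapse = ", ")))
  res <- wc_test(log(x), tau = tau, level = level)
  res$variant <- "poisson"
  res$q <- ncol(m)
  res
}

#' @export
print.wc_test <- function(x, digits = 4, ...) {
  cat(sprintf("Weighted CUSUM change-point test (%s, tau = %s)\n",
              x$variant, x$tau))
  cat(sprintf("  n = %d, q = %d; statistic = %.*g, sigma2 = %.*g\n",
              x$n, x$q, digits, x$statistic, digits, x$sigma2))
  cat(sprintf("  p-value = %.*g; critical value (level %.3g) = %.*g -> %s\n",
              digits, x$p.value, x$level, digits, x$critical.value,
              if (x$reject) "reject" else "do not reject"))
  cat(sprintf("  estimated change point: k = %d\n", x$k.hat))
  invisible(x)
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop_invalid("'level' must lie strictly in (0, 1)")
}
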