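#' Self-normalizing random weight at a split point
#'
#' The Shao-Zhang self-normalizer: for a candidate split k, the sum of the
#' forward within-segment CUSUM squares over 1..k and the backward ones over
#' k+1..n,
#' \deqn{w_k = \sum_{i=1}^{k} \Big\{S_i - \tfrac{i}{k} S_k\Big\}^2 +
#'       \sum_{i=k+1}^{n} \Big\{T_i - \tfrac{n-i+1}{n-k} T_{k+1}\Big\}^2,}
#' with \eqn{S_i = \sum_{j \le i} Y_{j\bullet}} and
#' \eqn{T_i = \sum_{j \ge i} Y_{j\bullet}}.  Dividing the squared global
#' CUSUM by this random norming removes the unknown long-run variance, so
#' the resulting statistics are pivotal under weak dependence (m-dependent,
#' mixing, or linear-process series).  Note: the display defining this
#' weight in the source literature contains an apparent typo (its first term
#' reduces to a scalar multiple of one sum); the construction implemented
#' here is the original Shao-Zhang normalizer, which that display is
#' presumed to intend.
#'
#' @param y numeric vector or n x q matrix (row means are used).
#' @param k split index, 1 <= k <= n-1.
#' @return Nonnegative scalar (0 for a constant series).
#' @export
selfnorm_weights <- function(y, k) {
  x <- row_mean_series(y)
  n <- length(x)
  if (k < 1 || k > n - 1 || k != round(k))
    stop_invalid("'k' must be an integer in 1..n-1")
  S <- cumsum(x)
  i <- seq_len(k)
  fwd <- sum((S[i] - (i / k) * S[k])^2)
  Tt <- rev(cumsum(rev(x)))            # T[i] = sum_{j >= i} x_j
  i2 <- (k + 1):n
  bwd <- sum((Tt[i2] - ((n - i2 + 1) / (n - k)) * Tt[k + 1])^2)
  fwd + bwd
}

#' Self-normalized weighted CUSUM test
#'
#' Computes the self-normalized sum and max statistics
#' \deqn{S_{n} = \sum_{k=1}^{n-1} \frac{1}{w_k}
#'       \Big(\sum_{i \le k} (Y_{i\bullet} - \bar Y_{\bullet\bullet})\Big)^2,
#'       \qquad
#'       M_{n} = \max_{k} \frac{n}{w_k}
#'       \Big(\sum_{i \le k} (Y_{i\bullet} - \bar Y_{\bullet\bullet})\Big)^2,}
#' with the random weights of [selfnorm_weights()].  Both are invariant to
#' location and scale changes of the series, and under weak dependence they
#' converge to pivotal functionals of a Brownian bridge; p-values are read
#' from the shipped Monte-Carlo quantile table of those limits (see
#' [selfnorm_limit_quantiles()]).  Split points with \eqn{w_k = 0} and a
#' zero numerator (flat segments) contribute 0/0 terms, which are dropped
#' with a warning; a zero weight against a nonzero numerator means the
#' series is degenerate and raises an error.
#'
#' @param y numeric vector or n x q matrix, n >= 4, non-constant rows.
#' @param level test level for the reported rejection decisions.
#' @return Object of class `"wc_selfnorm"`: list with `sn` and `mn`
#'   statistic values, `p.value.sn`, `p.value.mn`, critical values at
#'   `level`, `k.hat` (argmax of the max-statistic criterion), `n`, `q`.
#' @export
selfnorm_wc <- function(y, level = 0.05) {
  check_level(level)
  x <- row_mean_series(y)
  n <- length(x)
  q <- if (is.matrix(y) || is.data.frame(y)) ncol(y) else 1L
  if (n < 4) stop_invalid("need at least 4 time points")
  if (stats::var(x) == 0)
    stop_degenerate("constant series: self-normalized statistics undefined")
  num <- cumsum(x - mean(x))[seq_len(n - 1)]^2
  w <- vapply(seq_len(n - 1), function(k) selfnorm_weights(x, k), numeric(1))
  zero <- w == 0
  if (any(zero & num > 1e-12 * max(num)))
    stop_degenerate("zero self-normalizer against a nonzero CUSUM")
  if (any(zero)) {
    warning("dropping ", sum(zero), " split point(s) with 0/0 terms")
    num <- num[!zero]; w <- w[!zero]
  }
  ratio <- num / w
  sn <- sum(ratio)
  mn <- n * max(ratio)
  tab <- load_mc_table("selfnorm_limit_quantiles.csv")
  tsum <- tab[tab$statistic == "sum", ]
  tmax <- tab[tab$statistic == "max", ]
  res <- list(
    sn = sn, mn = mn,
    p.value.sn = table_pvalue(tsum, sn),
    p.value.mn = table_pvalue(tmax, mn),
    critical.sn = stats::approx(tsum$prob, tsum$quantile, 1 - level,
                                rule = 2)$y,
    critical.mn = stats::approx(tmax$prob, tmax$quantile, 1 - level,
                                rule = 2)$y,
    level = level,
    k.hat = which.max(ratio),
    n = n, q = q, variant = "selfnorm")
  structure(res, class = "wc_selfnorm")
}

#' @export
print.wc_selfnorm <- function(x, digits = 4, ...) {
  cat("Self-normalized weighted CUSUM test\n")
  cat(sprintf("  n = %d, q = %d\n", x$n, x$q))
  cat(sprintf("  sum statistic = %.*g, p-value = %.*g (crit %.3g)\n",
              digits, x$sn, digits, x$p.value.sn, x$critical.sn))
  cat(sprintf("  max statistic = %.*g, p-value = %.*g (crit %.3g)\n",
              digits, x$mn, digits, x$p.value.mn, x$critical.mn))
  cat(sprintf("  estimated change point: k = %d\n", x$k.hat))
  invisible(x)
}
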