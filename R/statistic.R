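#' Weighted CUSUM statistic
#'
#' \deqn{S_n(Y; \tau, \gamma) = \sum_{k=1}^{n-1} w_k^{-1}(\tau)
#'       \Big|\sum_{i \le k} (Y_i - \bar Y)\Big|^{\gamma}.}
#' For `gamma = 2` this equals the quadratic form \eqn{Y^\top Q Y} with
#' \eqn{Q} from [wc_quadform()].
#'
#' @param y numeric vector of length n >= 2.
#' @param scheme a `"wc_scheme"` (its `n` must match `length(y)`).
#' @return The statistic value (nonnegative for even `gamma`).
#' @examples
#' wc_statistic(c(0, 0, 3), weight_scheme(3, "center"))  # 2.5
#' @export
wc_statistic <- function(y, scheme) {
  stopifnot(inherits(scheme, "wc_scheme"))
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2) stop_invalid("'y' must have length >= 2")
  if (n != scheme$n)
    stop_invalid(sprintf("scheme built for n = %d but length(y) = %d",
                         scheme$n, n))
  cs <- cumsum(y - mean(y))[seq_len(n - 1)]
  sum(abs(cs)^scheme$gamma / scheme$w)
}

#' Plug-in variance estimator
#'
#' \eqn{\hat\sigma^2 = (n-1)^{-1} \sum_i (Y_i - \bar Y)^2}, the consistent
#' estimator used to studentize the WC statistic when \eqn{\sigma^2} is
#' unknown.
#'
#' @param y numeric vector, length >= 2, not constant.
#' @return Positive scalar.
#' @export
wc_variance <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 2) stop_invalid("'y' must have length >= 2")
  v <- stats::var(y)
  if (!is.finite(v) || v <= 0)
    stop_degenerate("constant series: the studentized statistic is undefined")
  v
}

#' Change-point location estimate
#'
#' \deqn{\hat k(\tau) = \arg\max_{1 \le k < n} w_k^{-1/2}(\tau)
#'       \Big|\sum_{i \le k} (Y_{i\bullet} - \bar Y_{\bullet\bullet})\Big|.}
#' The absolute value makes the estimate direction-agnostic (the sign of the
#' drift in the partial sums depends on the direction of the mean shift);
#' ties are broken to the smallest k.  On a constant series the criterion is
#' identically zero and k = 1 is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param y numeric vector, or an n x q matrix whose row means are used.
#' @param tau weight kind, or a `"wc_scheme"`.
#' @return Integer estimate in 1..n-1.
#' @examples
#' estimate_changepoint(rep(0:1, c(6, 6)), "center")  # 6
#' @export
estimate_changepoint <- function(y, tau = c("center", "left", "right")) {
  x <- row_mean_series(y)
  n <- length(x)
  if (n < 3) stop_invalid("need at least 3 time points")
  w <- if (inherits(tau, "wc_scheme")) {
    if (tau$n != n) stop_invalid("scheme length does not match the series")
    tau$w
  } else wc_weights(n, match.arg(tau))
  crit <- abs(cumsum(x - mean(x))[seq_len(n - 1)]) / sqrt(w)
  k <- which.max(crit)
  if (crit[k] == 0) {
    k <- 1L
    attr(k, "degenerate") <- TRUE
  }
  k
}

# rows = time; a vector is its own row-mean series
row_mean_series <- function(y) {
  if (is.matrix(y) || is.data.frame(y)) rowMeans(as.matrix(y))
  else as.numeric(y)
}
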