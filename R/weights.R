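#' Quadratic CUSUM weight scheme
#'
#' Constructs the weight scheme for the weighted CUSUM (WC) statistic.  The
#' weights \eqn{w_k(\tau) = -(k-\tau)^2 + \max\{\tau^2, (n-\tau)^2\}} are
#' quadratic in \eqn{k} with their symmetry centre at \eqn{\tau}, encoding a
#' prior guess of the change-point position:
#' \describe{
#'   \item{`"left"`}{\eqn{\tau = 0}: \eqn{w_k = (n+k)(n-k)}, decreasing in
#'     \eqn{k}.  The statistic divides by the weights, so the late partial
#'     sums get the largest influence: this scheme is most powerful for
#'     changes near the *end* of the series.}
#'   \item{`"center"`}{\eqn{\tau = n/2}: \eqn{w_k = k(n-k)}, the likelihood
#'     ratio weighting, most powerful for central changes.}
#'   \item{`"right"`}{\eqn{\tau = n}: \eqn{w_k = k(2n-k)}, increasing in
#'     \eqn{k}; most powerful for changes near the *beginning*.}
#' }
#' The `"left"`/`"right"` names refer to the position \eqn{\tau} of the
#' weight parabola's symmetry centre, not to the favoured change location.
#' \eqn{\tau} is represented categorically, so odd \eqn{n} poses no \eqn{n/2}
#' ambiguity: the centre formula \eqn{k(n-k)} is used verbatim for any
#' \eqn{n}.  One interpretation of \eqn{w_k} is the expected absorption time
#' of a simple random walk started at \eqn{k} (centre, \eqn{N = n}) or at
#' \eqn{k} resp. \eqn{n-k} on \eqn{2n} states.
#'
#' @param n integer series length, at least 2.
#' @param tau one of `"center"`, `"left"`, `"right"`.
#' @param gamma positive exponent applied to the absolute partial sums in the
#'   WC statistic; the default 2 targets mean changes and is the only value
#'   with an exact chi-squared-sum null distribution.
#' @return An object of class `"wc_scheme"`: a list with elements `n`, `tau`,
#'   `gamma`, and `w` (the weight vector \eqn{(w_1, \dots, w_{n-1})}).
#' @examples
#' weight_scheme(10, "center")$w[5]   # 5 * 5 = 25
#' weight_scheme(10, "left")$w[1]     # 11 * 9 = 99
#' @seealso [wc_weights()], [wc_quadform()], [wc_statistic()]
#' @export
weight_scheme <- function(n, tau = c("center", "left", "right"), gamma = 2) {
  tau <- match.arg(tau)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 || n != round(n))
    stop_invalid("'n' must be a single integer >= 2")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop_invalid("'gamma' must be a positive scalar")
  n <- as.integer(n)
  structure(list(n = n, tau = tau, gamma = gamma, w = wc_weights(n, tau)),
            class = "wc_scheme")
}

#' Weight vector of a WC scheme
#'
#' The quadratic weights \eqn{w_k(\tau)}, \eqn{k = 1, \dots, n-1}.  All are
#' strictly positive; the centre weights are symmetric
#' (\eqn{w_k = w_{n-k}}) and the left/right schemes mirror each other
#' (\eqn{w_k(\mathrm{left}) = w_{n-k}(\mathrm{right})}).
#'
#' @param n series length (integer >= 2), or a `"wc_scheme"`.
#' @param tau weight kind; ignored when `n` is a scheme.
#' @return Numeric vector of length `n - 1`.
#' @export
wc_weights <- function(n, tau = c("center", "left", "right")) {
  if (inherits(n, "wc_scheme")) return(n$w)
  tau <- match.arg(tau)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2)
    stop_invalid("'n' must be a single integer >= 2")
  n <- as.numeric(n)
  k <- seq_len(n - 1)
  switch(tau,
         center = k * (n - k),
         left   = (n + k) * (n - k),
         right  = k * (2 * n - k))
}

#' Quadratic-form matrix of the WC statistic
#'
#' For `gamma = 2` the WC statistic is the quadratic form
#' \eqn{S_n = Y^\top Q Y} with \eqn{n^2 Q = A A^\top},
#' \eqn{A = (A_1, \dots, A_{n-1})}, where column \eqn{A_k} has first \eqn{k}
#' entries \eqn{p_k^{1/2} (n-k)} and last \eqn{n-k} entries
#' \eqn{-p_k^{1/2} k}, with \eqn{p_k = 1/w_k(\tau)}.  \eqn{Q} is symmetric,
#' positive semidefinite, of rank \eqn{n-1}, annihilates the constant vector,
#' and its nonzero eigenvalues are the closed forms returned by
#' [wc_spectrum()].
#'
#' @param scheme a `"wc_scheme"` with `gamma = 2`.
#' @return The \eqn{n \times n} matrix \eqn{Q}, with the generating matrix
#'   \eqn{A} attached as attribute `"A"`.
#' @examples
#' Q <- wc_quadform(weight_scheme(2, "center"))
#' Q                       # [[1,-1],[-1,1]] / 4
#' eigen(Q)$values         # 1/2 and 0
#' @export
wc_quadform <- function(scheme) {
  stopifnot(inherits(scheme, "wc_scheme"))
  if (scheme$gamma != 2)
    stop_unsupported("the quadratic-form matrix Q is defined only for gamma = 2")
  n <- scheme$n
  p <- 1 / scheme$w
  k <- seq_len(n - 1)
  # A[i, k] = sqrt(p_k) * (n - k) for i <= k, -sqrt(p_k) * k for i > k
  A <- vapply(k, function(kk) {
    sqrt(p[kk]) * c(rep(n - kk, kk), rep(-kk, n - kk))
  }, numeric(n))
  Q <- tcrossprod(A) / n^2
  attr(Q, "A") <- A
  Q
}

#' @export
print.wc_scheme <- function(x, ...) {
  cat(sprintf("WC weight scheme: n = %d, tau = %s, gamma = %g\n",
              x$n, x$tau, x$gamma))
  invisible(x)
}

# typed error helpers shared across the package
stop_invalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("wc_invalid_input", "error", "condition")))
}
stop_unsupported <- function(msg) {
  stop(errorCondition(msg, class = c("wc_unsupported", "error", "condition")))
}
stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("wc_degenerate_data", "error", "condition")))
}
stop_numerical <- function(msg) {
  stop(errorCondition(msg, class = c("wc_numerical_error", "error", "condition")))
}
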