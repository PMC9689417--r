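#' Exact eigenvalue spectrum of the null WC distribution
#'
#' Under the normal model with known variance, \eqn{S_n(Y; \tau, 2)/\sigma^2}
#' is distributed as \eqn{\sum_{k=1}^{n-1} \lambda_k(\tau) Z_k^2} with
#' independent standard normal \eqn{Z_k} and closed-form eigenvalues
#' \deqn{\lambda_k(n/2) = \frac{1}{k(k+1)}, \qquad
#'       \lambda_k(0) = \lambda_k(n) = \frac{1}{2k(2k+1)},}
#' for \eqn{k = 1, \dots, n-1}.  The left and right schemes share one
#' spectrum, and the centre spectrum interleaves it:
#' \eqn{\lambda_{2k}(n/2) = \lambda_k(0)}.  Increasing \eqn{n} by one keeps
#' all existing eigenvalues and appends one new smallest term, so critical
#' values grow monotonically in \eqn{n} towards the limit spectrum.
#'
#' @param n integer series length >= 2.
#' @param tau weight kind, as in [weight_scheme()].
#' @return An object of class `"wc_spectrum"`: list with `lambda` (decreasing
#'   positive eigenvalues, length `n - 1`), `n`, `tau`, and tail-compensation
#'   fields `tail_mass`, `tail_m2` (both zero for finite `n`).
#' @examples
#' wc_spectrum(4, "center")$lambda   # 1/2, 1/6, 1/12
#' @seealso [wc_limit_spectrum()], [imhof_cdf()], [wc_critical_value()]
#' @export
wc_spectrum <- function(n, tau = c("center", "left", "right")) {
  tau <- match.arg(tau)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2)
    stop_invalid("'n' must be a single integer >= 2")
  k <- as.numeric(seq_len(n - 1))
  lambda <- if (tau == "center") 1 / (k * (k + 1)) else 1 / (2 * k * (2 * k + 1))
  new_spectrum(lambda, n = as.integer(n), tau = tau)
}

#' Truncated limit spectrum (n = Inf)
#'
#' The infinite-series limit of the null distribution, represented by its
#' first \eqn{K} eigenvalues.  The total mass is known exactly
#' (\eqn{\sum \lambda_k = 1} for the centre scheme by telescoping,
#' \eqn{1 - \log 2} for left/right), so \eqn{K} is the smallest truncation
#' point whose tail mass \eqn{\sum_{k > K} \lambda_k} falls below `epsilon`,
#' capped at `max_terms`.  Whatever mass remains beyond the explicit terms is
#' not discarded: it is carried in the spectrum object and compensated during
#' CDF evaluation by a single moment-matched chi-squared term plus a
#' deterministic shift (see [imhof_cdf()]), so the distributional error of
#' the representation is far below the tail mass itself.
#'
#' @param tau weight kind.
#' @param epsilon positive bound on the truncated tail mass (default 1e-8).
#' @param max_terms cap on the number of explicit eigenvalues retained.
#' @return A `"wc_spectrum"` with `n = Inf` and attribute `truncation` = K.
#' @examples
#' s <- wc_limit_spectrum("center", epsilon = 1e-4)
#' length(s$lambda)                      # 9999: tail 1/(K+1) <= 1e-4
#' sum(s$lambda) + s$tail_mass           # 1 (telescoping identity)
#' @export
wc_limit_spectrum <- function(tau = c("center", "left", "right"),
                              epsilon = 1e-8, max_terms = 16384L) {
  tau <- match.arg(tau)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop_invalid("'epsilon' must be a positive scalar")
  total <- if (tau == "center") 1 else 1 - log(2)
  k <- as.numeric(seq_len(max_terms))
  lam_all <- if (tau == "center") 1 / (k * (k + 1)) else 1 / (2 * k * (2 * k + 1))
  tail_after <- total - cumsum(lam_all)
  K <- which(tail_after < epsilon)[1]
  if (is.na(K)) K <- max_terms
  lambda <- lam_all[seq_len(K)]
  # second moment of the truncated tail, summed until increments vanish
  kk <- as.numeric((K + 1):(K + 2e6))
  lam_tail_sq <- if (tau == "center") 1 / (kk * (kk + 1))^2
                 else 1 / (2 * kk * (2 * kk + 1))^2
  sp <- new_spectrum(lambda, n = Inf, tau = tau,
                     tail_mass = max(total - sum(lambda), 0),
                     tail_m2 = sum(lam_tail_sq))
  attr(sp, "truncation") <- K
  sp
}

new_spectrum <- function(lambda, n, tau, tail_mass = 0, tail_m2 = 0) {
  structure(list(lambda = lambda, n = n, tau = tau,
                 tail_mass = tail_mass, tail_m2 = tail_m2),
            class = "wc_spectrum")
}

#' @export
print.wc_spectrum <- function(x, ...) {
  cat(sprintf("WC null spectrum: tau = %s, n = %s, %d explicit eigenvalues\n",
              x$tau, format(x$n), length(x$lambda)))
  if (x$tail_mass > 0)
    cat(sprintf("  truncated representation; compensated tail mass %.3g\n",
                x$tail_mass))
  invisible(x)
}

# Coerce x to a wc_spectrum: pass through, or treat a numeric vector as a
# bare eigenvalue list (used in tests against single-eigenvalue identities).
as_spectrum <- function(x) {
  if (inherits(x, "wc_spectrum")) return(x)
  if (is.numeric(x) && length(x) >= 1L && all(x > 0))
    return(new_spectrum(sort(as.numeric(x), decreasing = TRUE),
                        n = length(x) + 1L, tau = "custom"))
  stop_invalid("expected a 'wc_spectrum' or a positive numeric eigenvalue vector")
}
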