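#' Saddle-point approximation of the Poisson mixed-model integral
#'
#' Approximates
#' \deqn{I(\rho; a, b, \nu^2) = \int_{-\infty}^{\infty}
#'       \exp\Big\{-b e^u + a u - \frac{(u-\rho)^2}{2\nu^2}\Big\}\, du}
#' by the Laplace expansion around the saddle point \eqn{c = \log(a/b)} of
#' \eqn{\phi(u) = a u - b e^u}:
#' \deqn{I \approx \Big(\frac{a}{b e}\Big)^{a} \sqrt{\frac{2\pi}{a}}
#'       \exp\Big\{-\frac{(c-\rho)^2}{2\nu^2}\Big\}.}
#' With \eqn{a = q \bar Y_{i\bullet}}, \eqn{b = q}, this is the marginal
#' likelihood contribution of one time point in the Poisson mixed model, and
#' taking logs yields the Gaussian-in-\eqn{\log \bar Y_{i\bullet}} form that
#' justifies the log-transform in [poisson_wc_test()].  The relative error
#' decreases as \eqn{a} grows.  Provided for verification of that
#' derivation; the test itself uses the transform directly.
#'
#' @param rho location of the Gaussian factor.
#' @param a,b positive parameters of \eqn{\phi(u) = a u - b e^u}.
#' @param nu2 positive variance of the Gaussian factor.
#' @param log if `TRUE`, return the log of the approximation (the linear
#'   value overflows for large `a`).
#' @return Approximate integral value (or its log).
#' @export
saddlepoint_integral <- function(rho, a, b, nu2, log = FALSE) {
  if (!is.numeric(a) || a <= 0 || !is.numeric(b) || b <= 0 ||
      !is.numeric(nu2) || nu2 <= 0)
    stop_invalid("'a', 'b' and 'nu2' must be positive")
  cc <- base::log(a / b)
  lv <- a * (cc - 1) + 0.5 * (base::log(2 * pi) - base::log(a)) -
    (cc - rho)^2 / (2 * nu2)
  if (log) lv else exp(lv)
}
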