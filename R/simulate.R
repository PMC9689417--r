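# Synthetic-data generators for the designs used in the power studies, and
# the power-study harness itself.  All generators draw from R's global RNG;
# set.seed() (or the `seed` argument of power_study) controls
# reproducibility.

#' Normal mean-shift data
#'
#' Rows 1..k_star are i.i.d. N(0, 1); rows k_star+1..n are i.i.d.
#' N(delta, 1).  `delta = 0` gives pure null data.
#'
#' @param n number of time points.
#' @param q replicates per time point (columns).
#' @param k_star change-point location, 1 <= k_star <= n-1.
#' @param delta mean shift after the change point.
#' @return n x q numeric matrix.
#' @export
gen_normal_shift <- function(n, q, k_star, delta = 0) {
  check_kstar(n, k_star)
  y <- matrix(stats::rnorm(n * q), n, q)
  if (k_star < n) y[(k_star + 1):n, ] <- y[(k_star + 1):n, ] + delta
  y
}

#' Normal-mixture post-change data
#'
#' Rows up to k_star are standard normal; later rows are drawn from the
#' two-component normal mixture with the given weights and means and unit
#' component variances.  The implied mean shift is `sum(weights * means)`:
#' the study configurations (0.5, 0.5)/(0, 0.2) and (0.8, 0.2)/(0, 1)
#' correspond to shifts 0.1 and 0.2; other settings are accepted but
#' flagged with a message as non-standard.
#'
#' @inheritParams gen_normal_shift
#' @param weights mixture weights (length 2, summing to 1).
#' @param means component means (length 2).
#' @return n x q matrix with attribute `"delta"` (implied mean shift).
#' @export
gen_normal_mixture <- function(n, q, k_star, weights = c(0.8, 0.2),
                               means = c(0, 1)) {
  check_kstar(n, k_star)
  if (length(weights) != 2L || length(means) != 2L ||
      abs(sum(weights) - 1) > 1e-12 || any(weights < 0))
    stop_invalid("'weights' must be two nonnegative numbers summing to 1")
  std <- (isTRUE(all.equal(weights, c(0.5, 0.5))) &&
            isTRUE(all.equal(means, c(0, 0.2)))) ||
         (isTRUE(all.equal(weights, c(0.8, 0.2))) &&
            isTRUE(all.equal(means, c(0, 1))))
  if (!std) message("non-standard mixture configuration")
  y <- matrix(stats::rnorm(n * q), n, q)
  if (k_star < n) {
    npost <- (n - k_star) * q
    comp <- stats::rbinom(npost, 1, weights[2])
    y[(k_star + 1):n, ] <- y[(k_star + 1):n, ] +
      means[1] + comp * (means[2] - means[1])
  }
  structure(y, delta = sum(weights * means))
}

#' Poisson mixed-model counts
#'
#' Per-time latent effects \eqn{U_i \sim N(0, \nu^2)}; conditionally on
#' \eqn{U_i} the counts \eqn{Y_{ij}} are Poisson with mean
#' \eqn{\exp(\rho_i + U_i)}, where \eqn{\rho_i} steps from `rho_pre` to
#' `rho_post` after `k_star`.  `nu2 > 0` induces within-row dependence and
#' overdispersion of the row totals.
#'
#' @inheritParams gen_normal_shift
#' @param rho_pre,rho_post log-rates before/after the change.
#' @param nu2 latent-effect variance (>= 0).
#' @return n x q integer matrix.
#' @export
gen_poisson_mixed <- function(n, q, k_star, rho_pre = 0, rho_post = 0,
                              nu2 = 0.1) {
  check_kstar(n, k_star)
  if (nu2 < 0) stop_invalid("'nu2' must be nonnegative")
  rho <- rep(c(rho_pre, rho_post), c(k_star, n - k_star))
  u <- stats::rnorm(n, sd = sqrt(nu2))
  matrix(stats::rpois(n * q, lambda = rep(exp(rho + u), q)), n, q)
}

#' Weakly dependent (AR(1)) data
#'
#' Each column is an independent stationary AR(1) series with coefficient
#' `phi` and standard normal innovations (a linear process, satisfying the
#' weak-dependence conditions of the self-normalized test), so the row-mean
#' series is itself AR(1) with coefficient `phi`.  An optional mean shift
#' `delta` is added after `k_star`.
#'
#' @inheritParams gen_normal_shift
#' @param phi AR(1) coefficient, |phi| < 1.
#' @return n x q matrix.
#' @export
gen_ar1_weakdep <- function(n, q, k_star = n, phi = 0.3, delta = 0) {
  if (abs(phi) >= 1) stop_invalid("'phi' must satisfy |phi| < 1")
  check_kstar(n, k_star, allow_n = TRUE)
  e <- matrix(stats::rnorm(n * q), n, q)
  y <- apply(e, 2, function(col) {
    x <- stats::filter(col, phi, method = "recursive",
                       init = stats::rnorm(1, sd = 1 / sqrt(1 - phi^2)))
    as.numeric(x)
  })
  y <- matrix(y, n, q)
  if (delta != 0 && k_star < n) y[(k_star + 1):n, ] <- y[(k_star + 1):n, ] + delta
  y
}

#' Synthetic image sequence with arrival and departure
#'
#' Emulates a camera watching a scene that an object enters and later
#' leaves: n grayscale frames of pixel noise (flattened to q = width x
#' height columns), with a bright Gaussian blob added to frames k1+1..k2.
#' The arrival k1 sits near the start and the departure k2 near the end, so
#' the right-tail weight is suited to detecting the arrival on a prefix of
#' the sequence and the left-tail weight to detecting the departure on the
#' full sequence.
#'
#' @param n number of frames.
#' @param width,height frame dimensions in pixels.
#' @param k1,k2 arrival and departure frames, 1 <= k1 < k2 <= n - 1.
#' @param intensity peak brightness of the blob (0 = no change).
#' @param noise_sd pixel noise standard deviation.
#' @return n x (width*height) matrix with attributes `k1`, `k2`, `frame_dim`.
#' @export
gen_image_sequence <- function(n, width = 16, height = 16,
                               k1 = max(2, round(n * 0.08)),
                               k2 = round(n * 0.82),
                               intensity = 3, noise_sd = 1) {
  if (!(k1 >= 1 && k1 < k2 && k2 <= n - 1))
    stop_invalid("need 1 <= k1 < k2 <= n - 1")
  q <- width * height
  y <- matrix(stats::rnorm(n * q, sd = noise_sd), n, q)
  gx <- outer(seq_len(height), seq_len(width),
              function(r, c) exp(-((r - height / 2)^2 + (c - width / 2)^2) /
                                   (2 * (min(width, height) / 5)^2)))
  blob <- intensity * as.numeric(gx)
  frames <- (k1 + 1):k2
  y[frames, ] <- y[frames, ] + rep(blob, each = length(frames))
  structure(y, k1 = k1, k2 = k2, frame_dim = c(height, width))
}

#' Monte-Carlo power study
#'
#' Estimates rejection percentages of the WC tests (and optionally the
#' graph-based variants) on one simulation design cell.  Within each
#' replicate one dataset is generated and every requested method is applied
#' to it (common random numbers, so method comparisons are low-variance);
#' replicates use independent substreams derived from `seed` (a vector of
#' per-replicate seeds drawn once from the master seed), so results do not
#' depend on evaluation order.
#'
#' @param n,q,k_star,delta design cell; `delta` is the mean shift (for
#'   `model = "normal_mixture"` the mixture is chosen by `mixture_weights`
#'   and `mixture_means` and `delta` is ignored).
#' @param model `"normal_shift"` or `"normal_mixture"`.
#' @param methods subset of `"wc_left"`, `"wc_center"`, `"wc_right"`,
#'   `"graph_euclidean"`, `"graph_pseudo"`.
#' @param reps Monte-Carlo replicates (default 200, as in the reference
#'   power tables).
#' @param level test level.
#' @param seed master seed.
#' @param mixture_weights,mixture_means passed to [gen_normal_mixture()].
#' @param perm_reps permutation replicates for the graph methods.
#' @return Object of classes `"wc_power"`/`"data.frame"`: one row per
#'   method with the rejection percentage and its binomial standard error.
#' @export
power_study <- function(n, q, k_star, delta = 0,
                        model = c("normal_shift", "normal_mixture"),
                        methods = c("wc_left", "wc_center", "wc_right"),
                        reps = 200L, level = 0.05, seed = 1L,
                        mixture_weights = c(0.8, 0.2),
                        mixture_means = c(0, 1),
                        perm_reps = 199L) {
  model <- match.arg(model)
  check_level(level)
  methods <- match.arg(methods, c("wc_left", "wc_center", "wc_right",
                                  "graph_euclidean", "graph_pseudo"),
                       several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  # exact critical values, computed once per weight kind
  wc_tau <- sub("^wc_", "", methods[startsWith(methods, "wc_")])
  crits <- vapply(unique(wc_tau), function(tau)
    wc_critical_value(1 - level, wc_spectrum(n, tau)), numeric(1))
  schemes <- lapply(stats::setNames(nm = unique(wc_tau)),
                    function(tau) weight_scheme(n, tau))
  rej <- matrix(FALSE, reps, length(methods),
                dimnames = list(NULL, methods))
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    y <- switch(model,
      normal_shift = gen_normal_shift(n, q, k_star, delta),
      normal_mixture = suppressMessages(
        gen_normal_mixture(n, q, k_star, mixture_weights, mixture_means)))
    x <- rowMeans(y)
    s2 <- stats::var(x)
    for (meth in methods) {
      rej[r, meth] <- if (startsWith(meth, "wc_")) {
        tau <- sub("^wc_", "", meth)
        wc_statistic(x, schemes[[tau]]) / s2 > crits[[tau]]
      } else {
        metric <- sub("^graph_", "", meth)
        gt <- graph_wc_test(y, metric = metric, tau = "center", gamma = 1,
                            level = level, calibration = "permutation",
                            perm_reps = perm_reps)
        gt$p.value < level
      }
    }
  }
  phat <- colMeans(rej)
  structure(
    data.frame(method = methods,
               model = model, n = n, q = q, k_star = k_star,
               delta = if (model == "normal_mixture")
                 sum(mixture_weights * mixture_means) else delta,
               reps = reps, level = level,
               power_pct = 100 * phat,
               se_pct = 100 * sqrt(phat * (1 - phat) / reps),
               row.names = NULL),
    class = c("wc_power", "data.frame"))
}

check_kstar <- function(n, k_star, allow_n = FALSE) {
  hi <- if (allow_n) n else n - 1
  if (!is.numeric(k_star) || length(k_star) != 1L || k_star < 1 ||
      k_star > hi || k_star != round(k_star))
    stop_invalid(sprintf("'k_star' must be an integer in 1..%d", hi))
}
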