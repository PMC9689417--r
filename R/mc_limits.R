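# Monte-Carlo quantile tables for the two limit laws without closed forms:
# the self-normalized WC limits (integral and max of a squared Brownian
# bridge over the Shao-Zhang random norming) and the graph-variant limit
# functionals of Eqs.-style weighted bridge integrals.  Default tables are
# shipped as plain-text CSVs under inst/extdata (grid 2000, 1e5 replicates,
# seed 20220) and can be regenerated with the exported functions below.

.mc_defaults <- list(grid = 2000L, reps = 100000L, seed = 20220L)

# one chunk of discretized Brownian bridges: m x B matrix, row i = B(i/m)
bridge_chunk <- function(m, B) {
  W <- apply(matrix(stats::rnorm(m * B, sd = 1 / sqrt(m)), m, B), 2, cumsum)
  W - outer(seq_len(m) / m, W[m, ])
}

#' Monte-Carlo quantiles of the self-normalized WC limit laws
#'
#' Simulates the limit distributions of the self-normalized statistics
#' [selfnorm_wc()]: the integral \eqn{\int_0^1 \{B(t)-tB(1)\}^2 /
#' (D_{1,0,t} + D_{2,t,1})\, dt} and its max-over-t analogue, where
#' \eqn{D_{1,0,t}} and \eqn{D_{2,t,1}} are the forward and backward
#' within-segment squared-bridge integrals.  The bridge is discretized on a
#' uniform grid; the D-functionals are computed by prefix sums, so cost is
#' linear in the grid size per replicate.
#'
#' @param probs probabilities at which quantiles are reported.
#' @param grid number of discretization points of the bridge.
#' @param reps Monte-Carlo replicates.
#' @param seed RNG seed (the shipped default table uses 20220).
#' @return data.frame with columns `statistic` ("sum"/"max"), `prob`,
#'   `quantile`.
#' @export
selfnorm_limit_quantiles <- function(probs = default_prob_grid(),
                                     grid = 2000L, reps = 100000L,
                                     seed = 20220L) {
  set.seed(seed)
  m <- as.integer(grid)
  s <- seq_len(m) / m
  ssq <- cumsum(s^2)
  rssq <- rev(cumsum(rev((1 - s)^2)))
  sum_stat <- numeric(reps); max_stat <- numeric(reps)
  done <- 0L
  while (done < reps) {
    B <- min(200L, reps - done)
    bb <- bridge_chunk(m, B)
    for (j in seq_len(B)) {
      b <- bb[, j]
      C2 <- cumsum(b^2); Cs <- cumsum(s * b)
      R2 <- rev(cumsum(rev(b^2))); Rs <- rev(cumsum(rev((1 - s) * b)))
      k <- seq_len(m - 1)
      tk <- s[k]
      D1 <- (C2[k] - 2 * b[k] / tk * Cs[k] + (b[k] / tk)^2 * ssq[k]) / m
      D2 <- (R2[k + 1] - 2 * b[k] / (1 - tk) * Rs[k + 1] +
               (b[k] / (1 - tk))^2 * rssq[k + 1]) / m
      r <- b[k]^2 / (D1 + D2)
      sum_stat[done + j] <- sum(r) / m
      max_stat[done + j] <- max(r)
    }
    done <- done + B
  }
  rbind(
    data.frame(statistic = "sum", prob = probs,
               quantile = as.numeric(stats::quantile(sum_stat, probs, type = 8))),
    data.frame(statistic = "max", prob = probs,
               quantile = as.numeric(stats::quantile(max_stat, probs, type = 8))))
}

#' Monte-Carlo quantiles of the graph-variant limit functionals
#'
#' Simulates the limiting null functionals of the centred edge-count WC
#' statistic along a path graph.  Writing \eqn{\xi(t) = \{B(t)-tB(1)\}^2 -
#' t(1-t)} and \eqn{f(t)} for the limiting weight shape (\eqn{1-t^2} left,
#' \eqn{t(1-t)} centre, \eqn{2t-t^2} right), the simulated laws are
#' \deqn{\gamma = 1:\ \int_0^1 \xi(t)/f(t)\,dt, \qquad
#'       \gamma = 2:\ \int_0^1 \xi(t)^2/f(t)\,dt.}
#' The gamma = 1 law is the bridge functional \eqn{\int B_b^2/f} plus the
#' additive constant \eqn{\log 2 - 1} (left/right) or \eqn{-1} (centre);
#' those constants are exactly \eqn{-\int t(1-t)/f\,dt}, i.e. they centre
#' the functional, so the law has mean zero.  See [graph_wc_test()] for the
#' finite-sample normings that map the observed statistic onto these laws.
#'
#' @param tau weight kind.
#' @param gamma 1 or 2.
#' @inheritParams selfnorm_limit_quantiles
#' @return data.frame with columns `tau`, `gamma`, `prob`, `quantile`.
#' @export
graph_limit_mc <- function(tau = c("center", "left", "right"), gamma,
                           probs = default_prob_grid(), grid = 2000L,
                           reps = 100000L, seed = 20220L) {
  tau <- match.arg(tau)
  if (!gamma %in% c(1, 2)) stop_invalid("'gamma' must be 1 or 2")
  set.seed(seed)
  m <- as.integer(grid)
  t <- (seq_len(m - 1)) / m
  f <- switch(tau, left = 1 - t^2, center = t * (1 - t), right = 2 * t - t^2)
  out <- numeric(reps)
  done <- 0L
  while (done < reps) {
    B <- min(500L, reps - done)
    bb <- bridge_chunk(m, B)[seq_len(m - 1), , drop = FALSE]
    xi <- bb^2 - t * (1 - t)
    v <- if (gamma == 1) colSums(xi / f) / m else colSums(xi^2 / f) / m
    out[done + seq_len(B)] <- v
    done <- done + B
  }
  data.frame(tau = tau, gamma = gamma, prob = probs,
             quantile = as.numeric(stats::quantile(out, probs, type = 8)))
}

#' Quantile of a graph-variant limit law
#'
#' Looks up (by monotone interpolation in the shipped Monte-Carlo table) the
#' `p`-quantile of the limiting law used by the asymptotic calibration of
#' [graph_wc_test()].  With non-default `grid`/`reps`/`seed` the table is
#' recomputed by [graph_limit_mc()].
#'
#' @param tau weight kind.
#' @param gamma 1 or 2.
#' @param p probability (vectorized) in (0, 1).
#' @inheritParams selfnorm_limit_quantiles
#' @return Numeric quantile(s).
#' @export
graph_limit_quantiles <- function(tau = c("center", "left", "right"), gamma,
                                  p, grid = 2000L, reps = 100000L,
                                  seed = 20220L) {
  tau <- match.arg(tau)
  if (any(p <= 0 | p >= 1)) stop_invalid("'p' must lie strictly in (0, 1)")
  default <- identical(as.integer(grid), .mc_defaults$grid) &&
    identical(as.integer(reps), .mc_defaults$reps) &&
    identical(as.integer(seed), .mc_defaults$seed)
  tab <- if (default) {
    t0 <- load_mc_table("graph_limit_quantiles.csv")
    t0[t0$tau == tau & t0$gamma == gamma, ]
  } else {
    graph_limit_mc(tau, gamma, grid = grid, reps = reps, seed = seed)
  }
  stats::approx(tab$prob, tab$quantile, xout = p, rule = 2)$y
}

default_prob_grid <- function() {
  sort(unique(c(seq(0.01, 0.99, by = 0.01), seq(0.991, 0.999, by = 0.001))))
}

.mc_table_cache <- new.env(parent = emptyenv())

load_mc_table <- function(file) {
  if (!is.null(.mc_table_cache[[file]])) return(.mc_table_cache[[file]])
  path <- system.file("extdata", file, package = "wcusum")
  if (path == "")
    stop_numerical(sprintf("shipped Monte-Carlo table '%s' not found", file))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .mc_table_cache[[file]] <- tab
  tab
}

# p-value (upper tail) from a quantile table: interpolate prob as a function
# of quantile; outside the tabulated range, clamp to the nearest bound.
table_pvalue <- function(tab, x) {
  Fx <- stats::approx(tab$quantile, tab$prob, xout = x, rule = 2)$y
  pmin(pmax(1 - Fx, 1 - max(tab$prob)), 1)
}
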