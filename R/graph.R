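#' Distance matrix between time points
#'
#' Distances between the n rows of the data matrix, used to build the
#' similarity graph of the graph-based WC test.  `"euclidean"` uses the full
#' q-dimensional Euclidean distance (sensitive to both mean and variance
#' changes); `"pseudo"` uses \eqn{|\bar Y_{i_1\bullet} - \bar
#' Y_{i_2\bullet}|}, the distance between row means (sensitive to mean
#' changes only).  For q = 1 the two coincide.
#'
#' @param y n x q matrix (or vector), rows = time points; n >= 3.
#' @param metric `"euclidean"` or `"pseudo"`.
#' @return n x n symmetric matrix with zero diagonal and attribute
#'   `"metric"`.
#' @export
wc_distance <- function(y, metric = c("euclidean", "pseudo")) {
  metric <- match.arg(metric)
  m <- as.matrix(y)
  if (nrow(m) < 3) stop_invalid("need at least 3 time points")
  D <- if (metric == "euclidean") as.matrix(stats::dist(m)) else {
    x <- rowMeans(m)
    abs(outer(x, x, "-"))
  }
  dimnames(D) <- NULL
  attr(D, "metric") <- metric
  D
}

#' Shortest Hamiltonian path (heuristic)
#'
#' Orders the n observations along a short Hamiltonian path of the distance
#' graph: greedy edge insertion (all edges sorted by ascending length, ties
#' broken lexicographically by node pair; an edge is accepted unless it
#' would create a cycle or a degree-3 node) followed by 2-opt segment
#' reversals until no reversal shortens the path.  Fully deterministic for a
#' given matrix; the returned orientation starts at the endpoint with the
#' smaller index.
#'
#' @param D symmetric nonnegative distance matrix (e.g. [wc_distance()]).
#' @return Object of class `"wc_path"`: list with `order` (node permutation)
#'   and `length` (total path length).
#' @export
shp_order <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || n < 2) stop_invalid("'D' must be a square matrix, n >= 2")
  iu <- which(upper.tri(D))
  ii <- row(D)[iu]; jj <- col(D)[iu]
  ord <- order(D[iu], ii, jj)
  deg <- integer(n); comp <- seq_len(n)
  nbr <- matrix(0L, n, 2)
  nedge <- 0L
  for (e in ord) {
    i <- ii[e]; j <- jj[e]
    if (deg[i] >= 2L || deg[j] >= 2L || comp[i] == comp[j]) next
    nbr[i, deg[i] + 1L] <- j; nbr[j, deg[j] + 1L] <- i
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    comp[comp == comp[j]] <- comp[i]
    nedge <- nedge + 1L
    if (nedge == n - 1L) break
  }
  p <- walk_path(nbr, deg, n)
  p <- two_opt(p, D)
  if (p[1] > p[n]) p <- rev(p)
  structure(list(order = p, length = path_length(p, D)), class = "wc_path")
}

walk_path <- function(nbr, deg, n) {
  if (n == 2L) return(1:2)
  cur <- which(deg == 1L)[1]
  p <- integer(n); p[1] <- cur; prev <- 0L
  for (t in 2:n) {
    nb <- nbr[cur, ]
    nxt <- if (nb[1] != prev && nb[1] != 0L) nb[1] else nb[2]
    p[t] <- nxt; prev <- cur; cur <- nxt
  }
  p
}

path_length <- function(p, D) sum(D[cbind(p[-length(p)], p[-1])])

# best-improvement 2-opt sweeps; delta of reversing p[i..j] computed for all
# pairs at once by matrix indexing
two_opt <- function(p, D, max_sweeps = 4L * length(p)) {
  n <- length(p)
  if (n < 4) return(p)
  for (sweep in seq_len(max_sweeps)) {
    R <- D[p[-n], p, drop = FALSE]           # R[r, c] = D[p[r], p[c]]
    C <- D[p, p[-1], drop = FALSE]           # C[r, c] = D[p[r], p[c+1]]
    T1 <- rbind(0, R - R[cbind(seq_len(n - 1), 2:n)])
    T2 <- cbind(C - rep(C[cbind(seq_len(n - 1), seq_len(n - 1))],
                        each = n), 0)
    delta <- T1 + T2
    delta[!upper.tri(delta)] <- Inf
    best <- which.min(delta)
    if (delta[best] > -1e-12) break
    j <- ((best - 1L) %/% n) + 1L; i <- best - (j - 1L) * n
    p[i:j] <- p[j:i]
  }
  p
}

#' Between-group edge counts along a path
#'
#' For each split k, counts the path edges with one endpoint among the first
#' k time points and the other among the rest:
#' \eqn{C_P(N_k, \bar N_k) = \sum_i I\{(v_i, v_{i+1})\text{ straddles } k\}}.
#' Under the n! equally likely relabelings of the nodes the count has exact
#' permutation moments \eqn{E = 2k(n-k)/n} and
#' \eqn{Var = 2k(n-k)\{2k(n-k)-n\}/(n^3-n^2)}.
#'
#' @param path a `"wc_path"` (or bare node permutation).
#' @return Object of class `"wc_edgecount"`: list with `counts` (length
#'   n-1), `mean`, `variance` (the permutation moments), and `n`.
#' @export
edge_count_curve <- function(path) {
  p <- if (inherits(path, "wc_path")) path$order else as.integer(path)
  n <- length(p)
  if (n < 2 || !setequal(p, seq_len(n)))
    stop_invalid("'path' must be a permutation of 1..n")
  counts <- count_crossings(p[-n], p[-1], n)
  k <- as.numeric(seq_len(n - 1))
  structure(list(counts = counts,
                 mean = 2 * k * (n - k) / n,
                 variance = 2 * k * (n - k) * (2 * k * (n - k) - n) /
                   (n^3 - n^2),
                 n = n),
            class = "wc_edgecount")
}

# CP(k) for k = 1..n-1 from edge endpoint labels, in O(n + edges)
count_crossings <- function(a, b, n) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  cumsum(tabulate(lo, n) - tabulate(hi, n))[seq_len(n - 1)]
}

#' Graph-variant WC statistic
#'
#' \deqn{S_n(P; \tau, \gamma) = \sum_{k=1}^{n-1} w_k^{-1}(\tau)
#'       \Big(\frac{2k(n-k)}{n} - C_P(N_k, \bar N_k)\Big)^{\gamma}.}
#' A change point leaves few edges straddling the true split, so large
#' values are evidence against the null.  `gamma = 1` keeps the sign of the
#' centred counts (the statistic has exact permutation mean zero);
#' `gamma = 2` is nonnegative.
#'
#' @param curve a `"wc_edgecount"`.
#' @param scheme a `"wc_scheme"` with matching `n` and `gamma` 1 or 2.
#' @return Statistic value.
#' @export
graph_wc_statistic <- function(curve, scheme) {
  stopifnot(inherits(curve, "wc_edgecount"), inherits(scheme, "wc_scheme"))
  if (!scheme$gamma %in% c(1, 2))
    stop_invalid("graph statistic supports gamma = 1 or 2 only")
  if (scheme$n != curve$n)
    stop_invalid("scheme and edge-count curve disagree on n")
  dev <- curve$mean - curve$counts
  sum(dev^scheme$gamma / scheme$w)
}

#' Graph-based WC change-point test
#'
#' Pipeline: [wc_distance()] -> [shp_order()] -> [edge_count_curve()] ->
#' [graph_wc_statistic()], calibrated either by the exact permutation null
#' (default) or by the Brownian-bridge limit laws.
#'
#' Under the null the time labels are exchangeable given the path, so
#' resampling node labels gives the exact conditional null distribution of
#' the statistic; `calibration = "permutation"` uses `perm_reps` label
#' resamples.  `calibration = "asymptotic"` applies the limit normings
#' \eqn{(n/2)^{1/2} S_n} (gamma = 1) and \eqn{S_n/2} (gamma = 2) — derived
#' from the permutation variance of the centred counts, which scales as
#' \eqn{(2n)^{1/2}} at \eqn{k = tn} — and compares against the Monte-Carlo
#' quantiles of [graph_limit_mc()].  In our null simulations the centred
#' edge count is close to Gaussian rather than to the skewed bridge
#' functional, making the asymptotic calibration inaccurate at practical n;
#' it is provided for completeness and the permutation default is
#' recommended (see the package vignette).
#'
#' @param y n x q data matrix, rows = time; n >= 10 recommended.
#' @param metric distance kind, see [wc_distance()].
#' @param tau weight kind.
#' @param gamma 1 (signed) or 2 (squared centred counts).
#' @param level test level.
#' @param calibration `"permutation"` (exact, default) or `"asymptotic"`.
#' @param perm_reps number of label resamples for permutation calibration.
#' @return A `"wc_test"` with `variant = "graph"` and extra fields `metric`,
#'   `calibration`, `path`.
#' @export
graph_wc_test <- function(y, metric = c("euclidean", "pseudo"),
                          tau = c("center", "left", "right"), gamma = 1,
                          level = 0.05,
                          calibration = c("permutation", "asymptotic"),
                          perm_reps = 999L) {
  metric <- match.arg(metric)
  tau <- match.arg(tau)
  calibration <- match.arg(calibration)
  check_level(level)
  D <- wc_distance(y, metric)
  n <- nrow(D)
  path <- shp_order(D)
  curve <- edge_count_curve(path)
  scheme <- weight_scheme(n, tau, gamma = gamma)
  S <- graph_wc_statistic(curve, scheme)
  if (calibration == "permutation") {
    p <- path$order
    a0 <- p[-n]; b0 <- p[-1]
    perm <- vapply(seq_len(perm_reps), function(r) {
      L <- sample.int(n)
      cnt <- count_crossings(L[a0], L[b0], n)
      sum((curve$mean - cnt)^gamma / scheme$w)
    }, numeric(1))
    pval <- (1 + sum(perm >= S)) / (perm_reps + 1)
    crit <- as.numeric(stats::quantile(perm, 1 - level, type = 8))
    Tstat <- S
  } else {
    norm <- if (gamma == 1) sqrt(n / 2) else 0.5
    Tstat <- norm * S
    tab0 <- load_mc_table("graph_limit_quantiles.csv")
    tab <- tab0[tab0$tau == tau & tab0$gamma == gamma, ]
    pval <- table_pvalue(tab, Tstat)
    crit <- stats::approx(tab$prob, tab$quantile, 1 - level, rule = 2)$y
  }
  dev <- (curve$mean - curve$counts) / sqrt(scheme$w)
  res <- list(statistic = Tstat, sigma2 = NA_real_, p.value = pval,
              critical.value = crit, raw.statistic = S,
              level = level, k.hat = which.max(dev),
              n = n, q = ncol(as.matrix(y)), tau = tau, gamma = gamma,
              variant = "graph", metric = metric, calibration = calibration,
              path = path)
  res$reject <- res$p.value < level
  structure(res, class = "wc_test")
}
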