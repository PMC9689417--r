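# Independent brute-force oracles used across the suite.

# literal evaluation of the weighted CUSUM sum, no shared code with
# wc_statistic beyond base R
brute_wc <- function(y, tau, gamma = 2) {
  n <- length(y)
  tot <- 0
  for (k in 1:(n - 1)) {
    w <- switch(tau,
                center = k * (n - k),
                left = (n + k) * (n - k),
                right = k * (2 * n - k))
    ps <- 0
    for (i in 1:k) ps <- ps + (y[i] - mean(y))
    tot <- tot + abs(ps)^gamma / w
  }
  tot
}

# literal double-sum evaluation of the self-normalizer at split k
brute_selfnorm <- function(y, k) {
  n <- length(y)
  fwd <- 0
  for (i in 1:k) {
    si <- sum(y[1:i]); sk <- sum(y[1:k])
    fwd <- fwd + (si - (i / k) * sk)^2
  }
  bwd <- 0
  for (i in (k + 1):n) {
    ti <- sum(y[i:n]); tk <- sum(y[(k + 1):n])
    bwd <- bwd + (ti - (n - i + 1) / (n - k) * tk)^2
  }
  fwd + bwd
}

# literal edge-crossing count for one split
brute_edge_count <- function(path, k) {
  n <- length(path)
  cnt <- 0
  for (i in 1:(n - 1)) {
    a <- path[i]; b <- path[i + 1]
    if ((a <= k && b > k) || (b <= k && a > k)) cnt <- cnt + 1
  }
  cnt
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in 1:n) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out <- rbind(out, block)
  }
  out
}

# closed-form eigenvalues of the null spectrum
closed_lambda <- function(n, tau) {
  k <- as.numeric(1:(n - 1))
  if (tau == "center") 1 / (k * (k + 1)) else 1 / (2 * k * (2 * k + 1))
}

# finite-n Table-style critical value straight from the spectrum
critval <- function(p, n, tau) wc_critical_value(p, wc_spectrum(n, tau))
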