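test_that("distance matrices: symmetry, diagonal, q = 1 reduction", {
  set.seed(601)
  Y <- matrix(rnorm(8 * 5), 8, 5)
  for (metric in c("euclidean", "pseudo")) {
    D <- wc_distance(Y, metric)
    expect_equal(D, t(D))
    expect_equal(diag(D), rep(0, 8))
    expect_true(all(D >= 0))
  }
  Y[3, ] <- Y[5, ]
  expect_equal(wc_distance(Y, "euclidean")[3, 5], 0)
  y1 <- matrix(rnorm(6), ncol = 1)
  expect_equal(wc_distance(y1, "euclidean"), wc_distance(y1, "pseudo"),
               ignore_attr = TRUE)
  expect_equal(wc_distance(y1, "pseudo")[1, 2], abs(y1[1] - y1[2]),
               ignore_attr = TRUE)
})

test_that("SHP heuristic sorts collinear points and is optimal at n = 3", {
  pos <- c(5, 1, 3, 2, 4)
  D <- wc_distance(matrix(pos, ncol = 1), "pseudo")
  p <- shp_order(D)$order
  expect_true(identical(order(pos), p) || identical(rev(order(pos)), p))
  # n = 3 exhaustive: 3 distinct paths
  set.seed(602)
  for (rep in 1:20) {
    D3 <- wc_distance(matrix(rnorm(3 * 2), 3, 2), "euclidean")
    best <- min(D3[1, 2] + D3[2, 3], D3[2, 1] + D3[1, 3], D3[1, 3] + D3[3, 2])
    expect_equal(shp_order(D3)$length, best, tolerance = 1e-12)
  }
})

test_that("SHP path is never longer than the identity-order path", {
  set.seed(603)
  for (rep in 1:100) {
    n <- sample(5:15, 1)
    D <- wc_distance(matrix(rnorm(n * 3), n, 3), "euclidean")
    naive <- sum(D[cbind(1:(n - 1), 2:n)])
    expect_lte(shp_order(D)$length, naive + 1e-12)
  }
})

test_that("edge counts: identity path, closed-form mean, brute force", {
  ec <- edge_count_curve(1:12)
  expect_equal(ec$counts, rep(1, 11))
  expect_equal(edge_count_curve(1:10)$mean[5], 5)
  set.seed(604)
  p <- sample(9)
  ec2 <- edge_count_curve(p)
  for (k in 1:8) expect_equal(ec2$counts[k], brute_edge_count(p, k))
})

test_that("exhaustive permutation moments match the closed forms", {
  n <- 6
  perms <- all_perms(n)
  counts <- t(apply(perms, 1, function(p) edge_count_curve(p)$counts))
  ref <- edge_count_curve(1:n)
  expect_equal(colMeans(counts), ref$mean, tolerance = 1e-12)
  vperm <- apply(counts, 2, function(v) mean((v - mean(v))^2))
  expect_equal(vperm, ref$variance, tolerance = 1e-12)
})

test_that("graph statistic: zero at the mean, reversal and hand value", {
  sch <- weight_scheme(6, "center", gamma = 2)
  ec <- edge_count_curve(1:6)
  flat <- ec; flat$counts <- flat$mean
  expect_equal(graph_wc_statistic(flat, sch), 0)
  sch1 <- weight_scheme(6, "center", gamma = 1)
  expect_equal(graph_wc_statistic(flat, sch1), 0)
  # identity path, n = 4, center, gamma = 2: CP = 1, means (3/2, 2, 3/2),
  # weights (3, 4, 3)
  val <- (1 / 2)^2 / 3 + 1^2 / 4 + (1 / 2)^2 / 3
  expect_equal(graph_wc_statistic(edge_count_curve(1:4),
                                  weight_scheme(4, "center", gamma = 2)),
               val)
  # reversing the path leaves the edge set, hence the statistic, unchanged
  set.seed(605)
  p <- sample(10)
  for (g in 1:2) {
    s <- weight_scheme(10, "left", gamma = g)
    expect_equal(graph_wc_statistic(edge_count_curve(p), s),
                 graph_wc_statistic(edge_count_curve(rev(p)), s))
  }
  expect_error(graph_wc_statistic(ec, weight_scheme(6, "center", gamma = 3)),
               class = "wc_invalid_input")
})

test_that("centred counts follow the permutation scaling law", {
  # var of (E - CP) at k = n/2 grows like the closed-form permutation
  # variance, and the permutation shape is close to Gaussian (the basis for
  # preferring exact permutation calibration; see the vignette)
  set.seed(606)
  n <- 200
  z <- replicate(300, {
    y <- gen_normal_shift(n, 10, n / 2, 0)
    ec <- edge_count_curve(shp_order(wc_distance(y, "euclidean")))
    (ec$mean[n / 2] - ec$counts[n / 2])
  })
  vref <- edge_count_curve(1:n)$variance[n / 2]
  expect_lt(abs(var(z) / vref - 1), 0.25)
  skew <- mean((z - mean(z))^3) / sd(z)^3
  expect_lt(abs(skew), 0.5)
})

test_that("permutation-calibrated graph test holds its level", {
  set.seed(607)
  pv <- replicate(1000, {
    y <- gen_normal_shift(100, 10, 50, 0)
    graph_wc_test(y, "euclidean", "center", gamma = 1,
                  perm_reps = 199)$p.value
  })
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.03)
})

test_that("variance-only changes are visible to euclidean, not pseudo", {
  set.seed(608)
  gen_varshift <- function() {
    y <- matrix(rnorm(60 * 30), 60, 30)
    y[31:60, ] <- y[31:60, ] * sqrt(2)
    y
  }
  rej <- replicate(150, {
    y <- gen_varshift()
    c(eu = graph_wc_test(y, "euclidean", "center", gamma = 1,
                         perm_reps = 99)$p.value < 0.05,
      ps = graph_wc_test(y, "pseudo", "center", gamma = 1,
                         perm_reps = 99)$p.value < 0.05)
  })
  expect_gt(mean(rej["eu", ]), 0.4)          # clearly powered
  expect_lt(mean(rej["ps", ]), 0.15)         # near the level
})

test_that("asymptotic calibration pipeline is coherent", {
  set.seed(609)
  y <- gen_normal_shift(80, 20, 40, 1)
  res <- graph_wc_test(y, "pseudo", "center", gamma = 2,
                       calibration = "asymptotic")
  expect_equal(res$statistic, res$raw.statistic / 2)
  expect_true(res$p.value >= 0 && res$p.value <= 1)
  # against the heavier-tailed bridge-functional quantiles the asymptotic
  # calibration is conservative under the null (see the vignette)
  rej <- mean(replicate(200, {
    y0 <- gen_normal_shift(100, 10, 50, 0)
    graph_wc_test(y0, "euclidean", "center", gamma = 1,
                  calibration = "asymptotic")$p.value < 0.05
  }))
  expect_lt(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  qs <- graph_limit_quantiles("center", 2, c(0.5, 0.9, 0.99))
  expect_true(all(diff(qs) > 0))
  # gamma = 1 limit laws are mean-centred: estimate the mean by averaging
  # the quantile function over a uniform probability grid
  for (tau in c("left", "center")) {
    tab <- graph_limit_mc(tau, 1, probs = seq(0.005, 0.995, by = 0.01),
                          reps = 6000, seed = 11)
    expect_lt(abs(mean(tab$quantile)), 0.1)
  }
})
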