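test_that("matrix input with q = 1 reduces to the plain-series test", {
  set.seed(401)
  y <- rnorm(20)
  res <- wc_test(matrix(y, ncol = 1), "center")
  expect_equal(res$statistic,
               wc_statistic(y, weight_scheme(20, "center")) / wc_variance(y))
  expect_equal(res$q, 1L)
  expect_equal(res$n, 20L)
})

test_that("decision, p-value and critical value are consistent", {
  set.seed(402)
  for (tau in c("left", "center", "right")) {
    y <- c(rnorm(15), rnorm(15, 1.5))
    res <- wc_test(y, tau, level = 0.05)
    expect_identical(res$reject, res$statistic > res$critical.value)
    expect_identical(res$reject, res$p.value < res$level)
    expect_gte(res$statistic, 0)
    expect_true(res$p.value >= 0 && res$p.value <= 1)
  }
})

test_that("studentized statistic is location and scale invariant", {
  set.seed(403)
  y <- rnorm(25)
  base <- wc_test(y, "center")
  shifted <- wc_test(y + 10, "center")
  scaled <- wc_test(-2.5 * y, "center")
  expect_equal(shifted$statistic, base$statistic, tolerance = 1e-10)
  expect_equal(scaled$statistic, base$statistic, tolerance = 1e-10)
})

test_that("known-variance mode divides by sigma2 instead of the plug-in", {
  set.seed(404)
  y <- rnorm(18)
  res <- wc_test(y, "left", sigma2 = 1)
  expect_equal(res$statistic, wc_statistic(y, weight_scheme(18, "left")))
  expect_error(wc_test(y, "left", sigma2 = -1), class = "wc_invalid_input")
})

test_that("degenerate and undersized inputs raise typed errors", {
  expect_error(wc_test(rep(1, 10), "center"), class = "wc_degenerate_data")
  expect_error(wc_test(c(1, 2), "center"), class = "wc_invalid_input")
})

test_that("high signal-to-noise data recover the change point", {
  # noiseless step: exact recovery for every weight kind
  y <- rep(c(0, 1), c(10, 14))
  for (tau in c("left", "center", "right"))
    expect_equal(wc_test(y + 1e-9 * seq_along(y), tau)$k.hat, 10L)
  set.seed(405)
  Y <- gen_normal_shift(40, 50, 20, 3)
  res <- wc_test(Y, "center")
  expect_lte(abs(res$k.hat - 20), 2)
  expect_true(res$reject)
})

test_that("poisson variant transforms to log row means", {
  set.seed(406)
  cnt <- gen_poisson_mixed(30, 40, 15, rho_pre = 0, rho_post = 1, nu2 = 0.05)
  res <- poisson_wc_test(cnt, "center")
  ref <- wc_test(log(rowMeans(cnt)), "center")
  expect_equal(res$statistic, ref$statistic)
  expect_identical(res$variant, "poisson")
  # identical positive counts: raw weighted CUSUM of the log row means is 0
  flat <- matrix(5L, 10, 3)
  expect_equal(wc_statistic(log(rowMeans(flat)), weight_scheme(10, "center")), 0)
  expect_error(poisson_wc_test(flat, "center"), class = "wc_degenerate_data")
})

test_that("poisson variant rejects zero row means, naming them", {
  cnt <- matrix(1L, 6, 2)
  cnt[3, ] <- 0L
  err <- tryCatch(poisson_wc_test(cnt, "center"), error = identity)
  expect_s3_class(err, "wc_invalid_input")
  expect_match(conditionMessage(err), "3")
  expect_error(poisson_wc_test(matrix(-1, 5, 2)), class = "wc_invalid_input")
})

test_that("poisson mixed-model null is calibrated and power grows with q", {
  set.seed(407)
  crit <- critval(0.95, 40, "center")
  sch <- weight_scheme(40, "center")
  rej <- mean(replicate(2000, {
    cnt <- gen_poisson_mixed(40, 100, 20, rho_pre = 0.5, rho_post = 0.5,
                             nu2 = 0.1)
    x <- log(rowMeans(cnt))
    wc_statistic(x, sch) / wc_variance(x) > crit
  }))
  expect_lt(abs(rej - 0.05), 0.02)
  pow <- mean(replicate(100, {
    cnt <- gen_poisson_mixed(40, 100, 20, rho_pre = 0, rho_post = 0.5,
                             nu2 = 0.1)
    x <- log(rowMeans(cnt))
    wc_statistic(x, sch) / wc_variance(x) > crit
  }))
  expect_gt(pow, 0.9)
})
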