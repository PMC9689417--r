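test_that("generators are deterministic given the seed", {
  set.seed(701); a <- gen_normal_shift(20, 5, 10, 0.3)
  set.seed(701); b <- gen_normal_shift(20, 5, 10, 0.3)
  expect_identical(a, b)
  set.seed(701); c1 <- gen_poisson_mixed(10, 4, 5, 0, 1, 0.1)
  set.seed(701); c2 <- gen_poisson_mixed(10, 4, 5, 0, 1, 0.1)
  expect_identical(c1, c2)
})

test_that("normal shift: null moments and post-change block mean", {
  set.seed(702)
  y0 <- gen_normal_shift(100, 1000, 50, 0)
  expect_lt(abs(mean(y0)), 0.01)
  expect_lt(abs(var(as.numeric(y0)) - 1), 0.02)
  n <- 40; q <- 50; ks <- 10; d <- 0.7
  y <- gen_normal_shift(n, q, ks, d)
  post <- mean(y[(ks + 1):n, ])
  expect_lt(abs(post - d), 3 / sqrt(q * (n - ks)))
  expect_error(gen_normal_shift(10, 2, 10, 1), class = "wc_invalid_input")
})

test_that("mixture generator: implied shift and variance inflation", {
  set.seed(703)
  y1 <- suppressMessages(gen_normal_mixture(40, 2000, 20, c(0.5, 0.5), c(0, 0.2)))
  expect_equal(attr(y1, "delta"), 0.1)
  expect_lt(abs(mean(y1[21:40, ]) - 0.1), 0.02)
  y2 <- gen_normal_mixture(40, 2000, 20, c(0.8, 0.2), c(0, 1))
  expect_equal(attr(y2, "delta"), 0.2)
  expect_lt(abs(mean(y2[21:40, ]) - 0.2), 0.03)
  # mixture variance 1 + sum(w m^2) - (sum(w m))^2 = 1.16
  expect_lt(abs(var(as.numeric(y2[21:40, ])) - 1.16), 0.04)
  expect_message(gen_normal_mixture(10, 2, 5, c(0.6, 0.4), c(0, 1)),
                 "non-standard")
})

test_that("poisson mixed model: marginal mean and overdispersion", {
  set.seed(704)
  y <- gen_poisson_mixed(100, 1000, 50, rho_pre = 1, rho_post = 1, nu2 = 0)
  expect_lt(abs(mean(y) - exp(1)) / exp(1), 0.02)
  yo <- gen_poisson_mixed(200, 200, 100, rho_pre = 1, rho_post = 1, nu2 = 0.3)
  rt <- rowSums(yo)
  # with a latent row effect, var of row totals far exceeds the Poisson mean
  expect_gt(var(rt) / mean(rt), 2)
})

test_that("AR(1) generator: autocorrelation and long-run variance", {
  set.seed(705)
  y <- gen_ar1_weakdep(10000, 1, phi = 0.5)
  x <- as.numeric(y)
  expect_lt(abs(acf(x, plot = FALSE)$acf[2] - 0.5), 0.05)
  # long-run variance 1/(1-phi)^2 = 4 via batch means (batches of 90)
  bm <- colMeans(matrix(x[1:9000], 90))
  lrv <- var(bm) * 90
  expect_lt(abs(lrv - 4) / 4, 0.45)
  expect_error(gen_ar1_weakdep(10, 1, phi = 1), class = "wc_invalid_input")
})

test_that("image sequence: arrival/departure recovery by tail weights", {
  set.seed(706)
  y <- gen_image_sequence(50, 16, 16, k1 = 4, k2 = 41, intensity = 3)
  expect_identical(dim(y), c(50L, 256L))
  # right-tail weight on a prefix (frames 1..25) finds the arrival
  k1_hat <- wc_test(y[1:25, ], "right")$k.hat
  expect_lte(abs(k1_hat - 4), 2)
  # left-tail weight on the full sequence finds the departure
  k2_hat <- wc_test(y, "left")$k.hat
  expect_lte(abs(k2_hat - 41), 2)
  # zero intensity: no change, rejection at (or slightly below, given the
  # plug-in variance) the nominal level
  set.seed(707)
  rej <- mean(replicate(400, {
    y0 <- gen_image_sequence(30, 8, 8, k1 = 3, k2 = 25, intensity = 0)
    wc_test(y0, "center")$reject
  }))
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("power study: reproducibility, null level, monotonicity in delta", {
  ps1 <- power_study(40, 50, 20, 0.2, methods = "wc_center", reps = 50,
                     seed = 7)
  ps2 <- power_study(40, 50, 20, 0.2, methods = "wc_center", reps = 50,
                     seed = 7)
  expect_identical(ps1, ps2)
  null_ps <- power_study(40, 50, 20, 0, reps = 200, seed = 8)
  expect_true(all(abs(null_ps$power_pct / 100 - 0.05) <=
                    3 * sqrt(0.05 * 0.95 / 200)))
  # common random numbers across delta levels: power nondecreasing
  p_small <- power_study(40, 50, 20, 0.1, methods = "wc_center", reps = 100,
                         seed = 9)$power_pct
  p_big <- power_study(40, 50, 20, 0.2, methods = "wc_center", reps = 100,
                       seed = 9)$power_pct
  expect_gte(p_big, p_small)
})

test_that("studentized statistic diverges along n*q*delta^2 -> infinity", {
  set.seed(710)
  med_stat <- function(n, q, d) {
    median(replicate(40, {
      y <- gen_normal_shift(n, q, n / 2, d)
      x <- rowMeans(y)
      wc_statistic(x, weight_scheme(n, "center")) / var(x)
    }))
  }
  m <- c(med_stat(20, 20, 0.2), med_stat(40, 60, 0.3), med_stat(80, 160, 0.4))
  expect_true(all(diff(m) > 0))
  expect_gt(m[3] / m[1], 10)
})
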