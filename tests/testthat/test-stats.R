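test_that("variance estimators: closed forms and method-of-moments identity", {
  expect_equal(sigma2_hwe(0.5), 0.5)
  expect_equal(sigma2_hwe(0.2), 0.32)
  expect_equal(sigma2_hwe(0), 0)
  # variance of the counts {2,1,1,0} by hand: 6/4 - 1
  expect_equal(sigma2_mom(g1 = 2, g2 = 1, n_total = 4), 0.5)
  # constant genotype has zero variance
  expect_equal(sigma2_mom(g1 = 7, g2 = 0, n_total = 7), 0)
  # equals the divide-by-n sample variance of the reconstructed vector
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    g <- sample(0:2, n, replace = TRUE)
    expect_equal(
      sigma2_mom(sum(g == 1), sum(g == 2), n),
      mean(g^2) - mean(g)^2
    )
  }
  expect_error(sigma2_mom(1, 1, 0))
})

test_that("method-of-moments variance is unbiased for 2p(1-p) under HWE", {
  set.seed(99)
  p <- 0.3
  est <- replicate(400, {
    g <- rbinom(150, 2, p)
    sigma2_mom(sum(g == 1), sum(g == 2), 150)
  })
  # SE of the mean of 400 estimates ~ 0.002
  expect_lt(abs(mean(est) - sigma2_hwe(p)), 0.01)
})

test_that("trend statistic: hand value, zero at equality, antisymmetry, proportions-test equivalence", {
  expect_equal(trend_stat(c(2, 1), c(0, 1))$P, 1 / sqrt(0.5))
  g <- c(0, 1, 2, 1, 0)
  expect_equal(trend_stat(g, g)$P, 0)
  set.seed(7)
  for (i in 1:30) {
    case <- sample(0:2, sample(5:60, 1), replace = TRUE)
    ctrl <- sample(0:2, sample(5:60, 1), replace = TRUE)
    if (sum(c(case, ctrl)) %in% c(0, 2 * (length(case) + length(ctrl)))) next
    res <- trend_stat(case, ctrl)
    # allele-label swap negates P
    expect_equal(trend_stat(2 - case, 2 - ctrl)$P, -res$P)
    # equals the classical two-sample z-test of allele proportions (HWE mode)
    expect_equal(res$P, oracle_prop_z(case, ctrl))
  }
  expect_error(
    trend_stat(c(0, 0), c(0, 0)),
    class = "popfam_monomorphic"
  )
})

test_that("Wald transmission statistic: spot values and guards", {
  expect_equal(wald_stat(4, 2), 0)
  expect_equal(wald_stat(4, 3), 1) # 2 * 2 * (0.75 - 0.5)
  expect_equal(wald_stat(9, 9), 3) # maximal over-transmission
  # general p0 reduces to the p0 = 1/2 form
  expect_equal(wald_stat(16, 10, p0 = 0.5), 2 * sqrt(16) * (10 / 16 - 0.5))
  expect_error(wald_stat(0, 0), class = "popfam_no_transmissions")
  expect_error(wald_stat(4, 5))
  expect_error(wald_stat(4, 2, p0 = 1))
})

test_that("weight: harmonic-mean form, bounds and monotonicity in H", {
  expect_equal(compute_weight(200, 200, 100), 0.5)
  expect_equal(compute_weight(100, 100, 50), 0.5)
  expect_equal(compute_weight(123, 456, 0), 1)
  h <- 0:50
  w <- compute_weight(40, 60, h)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
})

test_that("combined statistic: null point, weight collapse, hand value, monotonicity", {
  expect_equal(popfam_stat(0, 0, 0.3, 0.7), 0)
  expect_equal(popfam_stat(2.5, -1, 1, 0.9), 2.5)
  expect_equal(popfam_stat(1, 1, 0.5, 0.5), 2 / sqrt(3))
  set.seed(11)
  for (i in 1:20) {
    w <- runif(1, 0.05, 0.95)
    tau <- runif(1)
    p <- rnorm(1)
    f <- rnorm(1)
    expect_gt(popfam_stat(p + 0.5, f, w, tau), popfam_stat(p, f, w, tau))
    expect_gt(popfam_stat(p, f + 0.5, w, tau), popfam_stat(p, f, w, tau))
  }
  # degenerate combination variance
  expect_error(popfam_stat(1, 1, 0.5, -1))
})

test_that("null covariance tau: analytic point, limits and range guard", {
  # at N = M with H at its HWE null expectation 2N * sigma2, tau = 1/2 exactly
  for (n in c(10, 200, 1234)) {
    for (s2 in c(0.1, 0.32, 0.5)) {
      expect_equal(compute_tau(n, n, 2 * n * s2, s2), 0.5)
    }
  }
  # small-H limit: vanishing shared information
  expect_lt(compute_tau(500, 500, 1, 0.5), 0.05)
  # M -> infinity limit: sqrt(H) / (2 * sqrt(N * sigma2))
  n <- 100
  h <- 30
  s2 <- 0.32
  expect_equal(
    compute_tau(n, 1e6, h, s2),
    sqrt(h) / (2 * sqrt(n * s2)),
    tolerance = 1e-4
  )
  # an H far above 2N forces tau > 1 and must be rejected
  expect_error(compute_tau(10, 10, 2000, 0.01))
})
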