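test_that("mixed_data derives counts and enforces invariants", {
  md <- mixed_data(
    trios = tibble::tibble(
      father_g = c(1, 2, 0), mother_g = c(1, 1, 0), child_g = c(1, 2, 0)
    ),
    controls = c(0, 1, 2, 0)
  )
  cts <- popfam:::md_counts(md)
  expect_equal(cts$N, 3)
  expect_equal(cts$M, 4)
  expect_equal(cts$H, 3) # two het parents in trio 1, one in trio 2
  expect_equal(cts$X, 2)
  expect_equal(cts$T_sum, 2) # trio1: t = 1, trio2: t = 2 - 1 = 1
  expect_true(cts$H <= 2 * cts$N && cts$X <= cts$N)
  expect_error(
    mixed_data(tibble::tibble(
      father_g = integer(0), mother_g = integer(0), child_g = integer(0)
    ), integer(0)),
    class = "popfam_empty"
  )
})

test_that("popfam_test combines the components and reports a two-sided normal p-value", {
  set.seed(3)
  md <- simulate_null_data(0.25, 150, 120)
  fit <- popfam_test(md)
  cts <- popfam:::md_counts(md)
  tr <- trend_stat(cts$case_g, cts$control_g)
  expect_equal(fit$P, tr$P)
  expect_equal(fit$F, wald_stat(cts$H, cts$T_sum))
  expect_equal(fit$tau, compute_tau(cts$N, cts$M, cts$H, tr$sigma2))
  expect_equal(fit$w, 0.5)
  expect_equal(fit$statistic, popfam_stat(fit$P, fit$F, 0.5, fit$tau))
  expect_equal(fit$p.value, 2 * pnorm(-abs(fit$statistic)))
  # sample-size weighting plugs the observed H into the harmonic-mean weight
  fit2 <- popfam_test(md, weight = "sample_size")
  expect_equal(fit2$w, compute_weight(cts$N, cts$M, cts$H))
  # fixed numeric weight
  fit3 <- popfam_test(md, w = 0.8)
  expect_equal(fit3$w, 0.8)
})

test_that("allele-label swap negates z and P and F but fixes the p-value", {
  set.seed(8)
  md <- simulate_null_data(0.35, 100, 100)
  swapped <- mixed_data(
    trios = dplyr::mutate(
      md$trios[, 1:3],
      dplyr::across(dplyr::everything(), ~ 2L - .x)
    ),
    controls = 2L - md$controls$g
  )
  a <- popfam_test(md)
  b <- popfam_test(swapped)
  expect_equal(b$statistic, -a$statistic)
  expect_equal(b$P, -a$P)
  expect_equal(b$F, -a$F)
  expect_equal(b$p.value, a$p.value)
})

test_that("degenerate datasets degrade gracefully", {
  # all parents homozygous: H = 0, test collapses to the trend statistic
  md <- mixed_data(
    trios = tibble::tibble(
      father_g = c(2, 0, 2), mother_g = c(0, 0, 2), child_g = c(1, 0, 2)
    ),
    controls = c(0, 0, 1, 0)
  )
  fit <- popfam_test(md)
  expect_equal(fit$w, 1)
  expect_equal(fit$tau, 0)
  expect_equal(fit$statistic, fit$P)
  expect_true("H0_fallback" %in% fit$flags)
  # monomorphic pooled sample but one informative transmission: F alone
  md2 <- mixed_data(
    trios = tibble::tibble(father_g = 1, mother_g = 0, child_g = 0),
    controls = c(0, 0, 0)
  )
  fit2 <- popfam_test(md2)
  expect_true("monomorphic" %in% fit2$flags)
  expect_equal(fit2$statistic, fit2$F)
  expect_equal(fit2$F, wald_stat(1, 0))
  # monomorphic and no transmissions: nothing to test
  md3 <- mixed_data(
    trios = tibble::tibble(father_g = 0, mother_g = 0, child_g = 0),
    controls = c(0, 0)
  )
  expect_error(popfam_test(md3), class = "popfam_degenerate")
})

test_that("missing genotypes: incomplete trios drop out of F but genotyped children stay in P", {
  md <- mixed_data(
    trios = tibble::tibble(
      father_g = c(1, NA, 1), mother_g = c(1, 1, 0), child_g = c(1, 2, NA)
    ),
    controls = c(0, 1, 0)
  )
  fit <- popfam_test(md)
  expect_equal(fit$N, 2) # children of trios 1 and 2
  expect_equal(fit$H, 2) # only trio 1 is complete
  expect_equal(fit$T_sum, 1)
})

test_that("tidy and glance return one-row tibbles with the documented columns", {
  set.seed(5)
  fit <- popfam_test(simulate_null_data(0.2, 60, 60))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(
    c("statistic", "p.value", "P", "F", "w", "tau", "N", "M", "H", "X") %in%
      names(td)
  ))
  gl <- glance(fit)
  expect_equal(gl$variance, "hwe")
  expect_equal(gl$statistic, fit$statistic)
})

test_that("combined null statistic is standard normal (KS) and the vectorized sampler agrees with popfam_test", {
  set.seed(31)
  s <- simulate_null_stats(4000, maf = 0.2, n_trios = 200, n_controls = 200)
  expect_gt(suppressWarnings(stats::ks.test(s$z, "pnorm"))$p.value, 0.01)
  # the vectorized sampler applies the same formulas as popfam_test
  set.seed(77)
  md <- simulate_null_data(0.2, 80, 90)
  fit <- popfam_test(md)
  cts <- popfam:::md_counts(md)
  expect_equal(
    fit$statistic,
    popfam_stat(
      fit$P, fit$F, 0.5,
      compute_tau(cts$N, cts$M, cts$H, fit$sigma2)
    )
  )
})
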