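test_that("haplotype frequencies: independence, perfect coupling, hand value, round-trip", {
  # D' = 0: product of margins
  hf <- haplotype_freqs(0.2, 0.3, 0)
  expect_equal(hf$freq[hf$marker == 1 & hf$disease == 1], 0.06)
  # perfect coupling at equal frequencies
  hf <- haplotype_freqs(0.2, 0.2, 1)
  expect_equal(hf$freq, c(0.2, 0, 0, 0.8))
  # hand arithmetic at the rare-allele setting
  hf <- haplotype_freqs(0.03, 0.03, 0.8)
  expect_equal(hf$freq[1], 0.03 * 0.03 + 0.8 * 0.03 * 0.97)
  # fuzz: margins, total mass and D' round-trip
  set.seed(19)
  for (i in 1:30) {
    pm <- runif(1, 0.02, 0.98)
    pd <- runif(1, 0.02, 0.98)
    dp <- runif(1)
    hf <- haplotype_freqs(pm, pd, dp)
    expect_equal(sum(hf$freq), 1, tolerance = 1e-12)
    expect_equal(sum(hf$freq[hf$marker == 1]), pm)
    expect_equal(sum(hf$freq[hf$disease == 1]), pd)
    dmax <- min(pm * (1 - pd), (1 - pm) * pd)
    expect_equal((hf$freq[1] - pm * pd) / dmax, dp, tolerance = 1e-9)
    expect_true(all(hf$freq >= 0))
  }
})

test_that("implied prevalence: closed form and the tuned scenario battery", {
  m <- genetic_model(daf = 0.03, f1 = 0.125, f2 = 0.440)
  expect_equal(prevalence(m), 0.0500115)
  expect_equal(round(prevalence(m), 2), 0.05)
  # no genetic effect: prevalence equals the common penetrance
  expect_equal(prevalence(genetic_model(0.2, 0.07, 0.07, f0 = 0.07)), 0.07)
  m6 <- genetic_model(daf = 0.30, f1 = 0.050, f2 = 0.080)
  expect_equal(prevalence(m6), 0.05025)
  # every scenario was tuned to a 5% prevalence with a 4.5% phenocopy rate
  sc <- popfam_scenarios()
  for (s in sc$scenario) {
    k <- prevalence(scenario_model(s))
    expect_gte(k, 0.0497)
    expect_lte(k, 0.0503)
  }
})

test_that("accepted-trio genotype distribution matches the exact conditional enumeration", {
  model <- scenario_model("S2")
  exact <- oracle_trio_dist(model)
  set.seed(101)
  tr <- simulate_trios(20000, model)
  key <- paste(tr$father_g, tr$mother_g, tr$child_g, sep = ":")
  obs <- table(factor(key, levels = names(exact))) / nrow(tr)
  # each cell within 4 binomial MC standard errors of the exact probability
  se <- sqrt(exact * (1 - exact) / nrow(tr))
  expect_true(all(abs(as.numeric(obs) - exact) <= 4 * se + 1e-9))
  # ascertainment enriches the offspring marker MAF above the population MAF
  exact_s1 <- oracle_trio_dist(scenario_model("S1"))
  child_g <- as.numeric(sub(".*:", "", names(exact_s1)))
  expect_gt(sum(child_g * exact_s1) / 2, 0.03)
})

test_that("with no LD the accepted trios are plain HWE draws", {
  model <- genetic_model(
    daf = 0.1, f1 = 0.2, f2 = 0.5, marker_maf = 0.25, dprime = 0
  )
  set.seed(55)
  tr <- simulate_trios(20000, model)
  obs <- table(factor(tr$father_g, levels = 0:2))
  expected <- c(0.75^2, 2 * 0.25 * 0.75, 0.25^2)
  gof <- stats::chisq.test(obs, p = expected)
  expect_gt(gof$p.value, 0.01)
})

test_that("controls: population mode is HWE, unaffected mode matches the exact conditional MAF", {
  model <- scenario_model("S1")
  set.seed(22)
  g <- simulate_controls(20000, model, mode = "population")
  expect_equal(mean(g) / 2, 0.03, tolerance = 0.15)
  gof <- stats::chisq.test(
    table(factor(g, levels = 0:2)),
    p = c(0.97^2, 2 * 0.03 * 0.97, 0.03^2)
  )
  expect_gt(gof$p.value, 0.01)
  exact <- oracle_control_dist(model)
  exact_maf <- sum(exact * 0:2) / 2
  expect_lt(exact_maf, 0.03) # healthy controls are slightly depleted
  g2 <- simulate_controls(20000, model, mode = "unaffected")
  se <- sqrt(exact_maf * (1 - exact_maf) / (2 * 20000))
  expect_lt(abs(mean(g2) / 2 - exact_maf), 4 * se)
})

test_that("null datasets: fair transmission, HWE heterozygosity, determinism", {
  set.seed(13)
  md <- simulate_null_data(0.3, 20000, 10)
  cts <- popfam:::md_counts(md)
  # transmissions from heterozygous parents are Binomial(H, 1/2)
  bt <- stats::binom.test(cts$T_sum, cts$H, p = 0.5)
  expect_gt(bt$p.value, 0.001)
  # E[H] / 2N approaches the HWE heterozygosity 2p(1-p)
  expect_equal(cts$H / (2 * cts$N), sigma2_hwe(0.3), tolerance = 0.03)
  # case and control allele frequencies agree in expectation
  set.seed(14)
  md2 <- simulate_null_data(0.2, 5000, 5000)
  expect_equal(
    mean(md2$trios$child_g), mean(md2$controls$g),
    tolerance = 0.03
  )
  # identical seeds reproduce datasets exactly
  set.seed(99)
  a <- simulate_null_data(0.2, 50, 50)
  set.seed(99)
  b <- simulate_null_data(0.2, 50, 50)
  expect_identical(a$trios, b$trios)
  expect_identical(a$controls, b$controls)
  set.seed(99)
  a2 <- simulate_alt_data(scenario_model("S3"), 40, 40)
  set.seed(99)
  b2 <- simulate_alt_data(scenario_model("S3"), 40, 40)
  expect_identical(a2$trios, b2$trios)
})

test_that("alternative datasets honour the size contract and reject empty requests", {
  set.seed(4)
  d <- simulate_alt_data(scenario_model("S4"), 37, 53)
  expect_equal(nrow(d$trios), 37)
  expect_equal(nrow(d$controls), 53)
  expect_error(
    simulate_alt_data(scenario_model("S1"), 0, 0),
    class = "popfam_empty"
  )
})
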