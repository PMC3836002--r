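#' Marker variance under Hardy-Weinberg equilibrium
#'
#' Variance of a per-person minor-allele count when genotype frequencies
#' follow HWE: `2 * p * (1 - p)`.
#'
#' @param maf Minor allele frequency, in `[0, 1]`. Vectorized.
#' @return Numeric vector of variances.
#' @seealso [sigma2_mom()] for the assumption-free estimator.
#' @export
#' @examples
#' sigma2_hwe(0.2)
sigma2_hwe <- function(maf) {
  if (!is.numeric(maf) || anyNA(maf) || any(maf < 0 | maf > 1)) {
    abort("`maf` must be numeric in [0, 1].")
  }
  2 * maf * (1 - maf)
}

#' Marker variance by the method of moments
#'
#' The divide-by-n sample variance of the per-person minor-allele count in
#' the pooled sample of cases and controls, computed from the genotype
#' counts alone: `(4 * g2 + g1 - n_total * gbar^2) / n_total` with
#' `gbar = (2 * g2 + g1) / n_total`. Used in place of [sigma2_hwe()] when
#' HWE cannot be assumed.
#'
#' @param g1,g2 Numbers of pooled individuals carrying exactly one and two
#'   copies of the minor allele.
#' @param n_total Total number of pooled individuals (cases + controls).
#' @return The estimated variance (non-negative).
#' @export
#' @examples
#' sigma2_mom(g1 = 2, g2 = 1, n_total = 4) # variance of counts {2,1,1,0}
sigma2_mom <- function(g1, g2, n_total) {
  if (any(n_total < 1)) abort("`n_total` must be at least 1.")
  if (any(g1 < 0) || any(g2 < 0) || any(g1 + g2 > n_total)) {
    abort("genotype counts must satisfy 0 <= g1 + g2 <= n_total.")
  }
  gbar <- (2 * g2 + g1) / n_total
  (4 * g2 + g1 - n_total * gbar^2) / n_total
}

#' Population-based trend statistic
#'
#' Compares the mean minor-allele count of cases against controls,
#' standardized to be asymptotically N(0, 1) under no association:
#' `P = (mean(R) - mean(S)) / sqrt(sigma2 * (1/N + 1/M))`. Under HWE this
#' equals the classical two-sample z-test of allele proportions.
#'
#' @param case_g,control_g Integer vectors of minor-allele counts (0, 1, 2)
#'   for cases and controls.
#' @param variance Variance estimator for the allele count: `"hwe"` uses
#'   `2p(1-p)` at the pooled allele frequency; `"mom"` uses the pooled
#'   method-of-moments sample variance ([sigma2_mom()]).
#' @return A one-row tibble with columns `P`, `sigma2` and `maf_hat`
#'   (pooled minor allele frequency).
#' @export
#' @examples
#' trend_stat(case_g = c(2, 1), control_g = c(0, 1))
trend_stat <- function(case_g, control_g, variance = c("hwe", "mom")) {
  variance <- match.arg(variance)
  case_g <- as.numeric(case_g)
  control_g <- as.numeric(control_g)
  check_gcounts(case_g, "case_g")
  check_gcounts(control_g, "control_g")
  n <- length(case_g)
  m <- length(control_g)
  if (n < 1 || m < 1) abort("need at least one case and one control.")
  pooled <- c(case_g, control_g)
  maf_hat <- mean(pooled) / 2
  sigma2 <- switch(variance,
    hwe = sigma2_hwe(maf_hat),
    mom = sigma2_mom(sum(pooled == 1), sum(pooled == 2), n + m)
  )
  if (sigma2 <= 0) {
    abort("marker is monomorphic in the pooled sample (sigma2 = 0).",
      class = "popfam_monomorphic"
    )
  }
  p_stat <- (mean(case_g) - mean(control_g)) / sqrt(sigma2 * (1 / n + 1 / m))
  tibble(P = p_stat, sigma2 = sigma2, maf_hat = maf_hat)
}

#' Family-based Wald statistic of Mendelian segregation
#'
#' Standardized excess transmission of the minor allele from heterozygous
#' parents to their affected offspring:
#' `F = (T - H * p0) / sqrt(H * p0 * (1 - p0))`, which at the null
#' transmission probability `p0 = 1/2` equals `2 * sqrt(H) * (T/H - 1/2)`
#' and squares to the classical TDT chi-square `(b - c)^2 / (b + c)` with
#' `b = T`, `c = H - T`.
#'
#' @param h_total Total number of heterozygous parents `H` (>= 1).
#'   Vectorized.
#' @param t_sum Total number of minor alleles transmitted from heterozygous
#'   parents, `0 <= t_sum <= h_total`.
#' @param p0 Null transmission probability, strictly inside (0, 1).
#' @return Numeric vector of Wald statistics, asymptotically N(0, 1) under
#'   Mendelian segregation.
#' @export
#' @examples
#' wald_stat(h_total = 4, t_sum = 3)
wald_stat <- function(h_total, t_sum, p0 = 0.5) {
  if (any(h_total < 1)) {
    abort("`h_total` must be >= 1 (no informative transmissions when H = 0).",
      class = "popfam_no_transmissions"
    )
  }
  if (any(t_sum < 0 | t_sum > h_total)) {
    abort("`t_sum` must lie in [0, h_total].")
  }
  if (any(p0 <= 0 | p0 >= 1)) abort("`p0` must be strictly inside (0, 1).")
  (t_sum - h_total * p0) / sqrt(h_total * p0 * (1 - p0))
}

#' Sample-size based weight for the combined statistic
#'
#' `w = A / (A + H)` where `A = N * M / (N + M)` is one half of the
#' harmonic mean of the numbers of cases and controls and `H` is the number
#' of heterozygous parents. Decreases toward 0 as family information grows;
#' equals 1 when there is none.
#'
#' @param n_cases,n_controls Numbers of cases (trio offspring) and controls.
#' @param h_total Number of heterozygous parents.
#' @return Weight in (0, 1]. Vectorized.
#' @export
#' @examples
#' compute_weight(200, 200, 100)
compute_weight <- function(n_cases, n_controls, h_total) {
  if (any(n_cases < 1) || any(n_controls < 1)) {
    abort("`n_cases` and `n_controls` must be >= 1.")
  }
  if (any(h_total < 0)) abort("`h_total` must be >= 0.")
  a <- n_cases * n_controls / (n_cases + n_controls)
  a / (a + h_total)
}

#' Null covariance between the trend and transmission statistics
#'
#' The two component statistics share the trio offspring as cases, so they
#' are positively correlated under the null. Conditional on the parental
#' genotypes, each case genotype decomposes into a deterministic
#' homozygous-parent contribution plus the transmissions from heterozygous
#' parents, giving `Cov(sum R, sum T) = H / 4` and hence, after
#' standardization,
#' `tau = sqrt(H) / (2 * N * sqrt(sigma2 * (1/N + 1/M)))`.
#'
#' @param n_cases,n_controls Numbers of cases and controls (>= 1).
#' @param h_total Number of heterozygous parents (>= 1 for a defined
#'   covariance; the combined test treats `H = 0` as `tau = 0`).
#' @param sigma2 Variance of the per-person allele count (> 0).
#' @return The covariance `tau`, in `[0, 1]`. Vectorized.
#' @export
#' @examples
#' # at N = M with H at its HWE null expectation 2 * N * sigma2, tau = 1/2
#' compute_tau(200, 200, h_total = 2 * 200 * 0.32, sigma2 = 0.32)
compute_tau <- function(n_cases, n_controls, h_total, sigma2) {
  if (any(n_cases < 1) || any(n_controls < 1)) {
    abort("`n_cases` and `n_controls` must be >= 1.")
  }
  if (any(h_total < 1)) abort("`h_total` must be >= 1.")
  if (any(sigma2 <= 0)) abort("`sigma2` must be > 0.")
  tau <- sqrt(h_total) /
    (2 * n_cases * sqrt(sigma2 * (1 / n_cases + 1 / n_controls)))
  if (any(tau < 0 | tau > 1 + 1e-12)) {
    abort("computed tau outside [0, 1]; check H and sigma2 inputs.")
  }
  pmin(tau, 1)
}

#' Combined POPFAM statistic
#'
#' Linear combination of the standardized population-based statistic `P`
#' and family-based statistic `F`, rescaled by their null covariance so
#' the result is N(0, 1) under no association:
#' `z = (w*P + (1-w)*F) / sqrt(w^2 + (1-w)^2 + 2*w*(1-w)*tau)`
#' (both components have unit null variance).
#'
#' @param p_stat,f_stat The component statistics. Vectorized.
#' @param w Weight on the population-based component, in `[0, 1]`.
#' @param tau Null covariance of the components, from [compute_tau()].
#' @return The combined z statistic.
#' @export
#' @examples
#' popfam_stat(1, 1, w = 0.5, tau = 0.5) # 2 / sqrt(3)
popfam_stat <- function(p_stat, f_stat, w, tau) {
  if (any(w < 0 | w > 1)) abort("`w` must lie in [0, 1].")
  denom2 <- w^2 + (1 - w)^2 + 2 * w * (1 - w) * tau
  if (any(denom2 <= 0)) {
    abort("degenerate combination: variance of the combined statistic is 0.")
  }
  (w * p_stat + (1 - w) * f_stat) / sqrt(denom2)
}

# shared genotype-count validation
check_gcounts <- function(g, what) {
  if (anyNA(g)) abort(paste0("`", what, "` contains missing values."))
  if (!all(g %in% c(0, 1, 2))) {
    abort(paste0("`", what, "` must contain allele counts 0, 1 or 2."))
  }
  invisible(g)
}
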