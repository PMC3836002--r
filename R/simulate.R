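# Conditional genotype simulation.
#
# Trios are sampled by rejection: parental haplotypes are drawn i.i.d. from
# the marker-disease haplotype frequencies (random mating), one haplotype
# per parent is transmitted uniformly at random, and the trio is accepted
# with probability equal to the offspring's penetrance at the disease
# locus, i.e. conditional on the offspring being affected. Only marker
# genotypes are returned. Controls are drawn the same way and accepted with
# probability one minus their penetrance (unaffected mode) or always
# (population mode). All draws use R's global RNG; set a seed for
# reproducible datasets.

# draw m candidate trios; returns marker genotypes + child disease genotype
draw_candidate_trios <- function(m, q, hap_marker, hap_disease) {
  idx <- matrix(sample.int(4L, 4L * m, replace = TRUE, prob = q), ncol = 4L)
  mk <- matrix(hap_marker[idx], ncol = 4L)
  dz <- matrix(hap_disease[idx], ncol = 4L)
  rows <- seq_len(m)
  from_f <- cbind(rows, 1L + (runif(m) < 0.5))          # father: col 1 or 2
  from_m <- cbind(rows, 3L + (runif(m) < 0.5))          # mother: col 3 or 4
  list(
    father_g = mk[, 1L] + mk[, 2L],
    mother_g = mk[, 3L] + mk[, 4L],
    child_g = mk[from_f] + mk[from_m],
    child_d = dz[from_f] + dz[from_m]
  )
}

#' Simulate ascertained case-parent trios
#'
#' Draws `n` trios whose offspring is affected, under a [genetic_model],
#' by rejection sampling (acceptance probability equals the offspring's
#' penetrance, so the long-run acceptance rate is the population
#' prevalence).
#'
#' @param n Number of accepted trios.
#' @param model A [genetic_model].
#' @param max_tries Guard against non-termination: abort after this many
#'   candidate draws per accepted trio on average.
#' @return A tibble with columns `father_g`, `mother_g`, `child_g` (marker
#'   minor-allele counts).
#' @export
#' @examples
#' set.seed(7)
#' simulate_trios(5, scenario_model("S1"))
simulate_trios <- function(n, model, max_tries = 1e6) {
  stopifnot(inherits(model, "genetic_model"))
  if (n < 1) abort("`n` must be >= 1.")
  q <- hap_probs(model$marker_maf, model$daf, model$dprime)
  hap_marker <- c(1L, 1L, 0L, 0L)
  hap_disease <- c(1L, 0L, 1L, 0L)
  pen <- c(model$f0, model$f1, model$f2)
  k <- max(prevalence(model), 1e-6)
  out_f <- integer(0)
  out_m <- integer(0)
  out_c <- integer(0)
  attempts <- 0
  while (length(out_c) < n) {
    m <- ceiling((n - length(out_c)) / k * 1.2) + 20L
    cand <- draw_candidate_trios(m, q, hap_marker, hap_disease)
    acc <- runif(m) < pen[cand$child_d + 1L]
    out_f <- c(out_f, cand$father_g[acc])
    out_m <- c(out_m, cand$mother_g[acc])
    out_c <- c(out_c, cand$child_g[acc])
    attempts <- attempts + m
    if (attempts > max_tries * n) {
      abort("rejection-sampling cap reached; penetrances may be ~0.")
    }
  }
  keep <- seq_len(n)
  tibble(
    father_g = out_f[keep], mother_g = out_m[keep], child_g = out_c[keep]
  )
}

#' Simulate unrelated controls
#'
#' Draws `n` unrelated individuals from the haplotype frequencies of a
#' [genetic_model] and returns their marker minor-allele counts. In
#' `"unaffected"` mode (the default) individuals are accepted with
#' probability one minus their penetrance, i.e. conditional on being
#' healthy; `"population"` mode ignores affection status.
#'
#' @param n Number of controls.
#' @param model A [genetic_model].
#' @param mode `"unaffected"` or `"population"`.
#' @param max_tries Rejection cap per accepted control.
#' @return Integer vector of marker allele counts.
#' @export
simulate_controls <- function(n, model, mode = c("unaffected", "population"),
                              max_tries = 1e6) {
  stopifnot(inherits(model, "genetic_model"))
  mode <- match.arg(mode)
  if (n < 1) abort("`n` must be >= 1.")
  q <- hap_probs(model$marker_maf, model$daf, model$dprime)
  hap_marker <- c(1L, 1L, 0L, 0L)
  hap_disease <- c(1L, 0L, 1L, 0L)
  pen <- c(model$f0, model$f1, model$f2)
  out <- integer(0)
  attempts <- 0
  k <- max(1 - prevalence(model), 1e-6)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / k * 1.2) + 20L
    idx <- matrix(sample.int(4L, 2L * m, replace = TRUE, prob = q), ncol = 2L)
    g <- matrix(hap_marker[idx], ncol = 2L)
    g <- g[, 1L] + g[, 2L]
    if (mode == "unaffected") {
      d <- matrix(hap_disease[idx], ncol = 2L)
      d <- d[, 1L] + d[, 2L]
      acc <- runif(m) < 1 - pen[d + 1L]
      g <- g[acc]
    }
    out <- c(out, g)
    attempts <- attempts + m
    if (attempts > max_tries * n) abort("rejection-sampling cap reached.")
  }
  out[seq_len(n)]
}

#' Simulate a mixed dataset under the null of no association
#'
#' Parents and controls are drawn from HWE at the given marker MAF and the
#' offspring genotype follows by fair Mendelian transmission; no disease
#' locus is involved, so the marker carries no association signal.
#'
#' @param maf Marker minor-allele frequency in (0, 1).
#' @param n_trios,n_controls Numbers of trios and controls.
#' @return A [mixed_data] object.
#' @export
#' @examples
#' set.seed(1)
#' simulate_null_data(0.2, n_trios = 50, n_controls = 50)
simulate_null_data <- function(maf, n_trios, n_controls) {
  if (maf <= 0 || maf >= 1) abort("`maf` must be strictly inside (0, 1).")
  if (n_trios < 1 || n_controls < 1) {
    abort("need at least one trio and one control.", class = "popfam_empty")
  }
  fg <- rbinom(n_trios, 2L, maf)
  mg <- rbinom(n_trios, 2L, maf)
  tf <- ifelse(fg == 1L, rbinom(n_trios, 1L, 0.5), fg %/% 2L)
  tm <- ifelse(mg == 1L, rbinom(n_trios, 1L, 0.5), mg %/% 2L)
  mixed_data(
    trios = tibble(father_g = fg, mother_g = mg, child_g = tf + tm),
    controls = rbinom(n_controls, 2L, maf)
  )
}

#' Simulate a mixed dataset under an alternative genetic model
#'
#' Combines [simulate_trios()] (affected-offspring ascertainment) and
#' [simulate_controls()] into one [mixed_data] object; the model and
#' control mode are recorded as attributes for provenance.
#'
#' @param model A [genetic_model].
#' @param n_trios,n_controls Numbers of trios and controls.
#' @param controls_mode Passed to [simulate_controls()].
#' @return A [mixed_data] object with attributes `model` and
#'   `controls_mode`.
#' @export
simulate_alt_data <- function(model, n_trios, n_controls,
                              controls_mode = c("unaffected", "population")) {
  controls_mode <- match.arg(controls_mode)
  if (n_trios < 1 || n_controls < 1) {
    abort("need at least one trio and one control.", class = "popfam_empty")
  }
  out <- mixed_data(
    trios = simulate_trios(n_trios, model),
    controls = simulate_controls(n_controls, model, mode = controls_mode)
  )
  attr(out, "model") <- model
  attr(out, "controls_mode") <- controls_mode
  out
}

#' Vectorized null sampling of the component statistics
#'
#' Draws many independent null datasets at once (HWE marker, fair
#' transmission) and returns the per-replicate component statistics,
#' closed-form covariance and combined statistic. This is the workhorse
#' behind large null-calibration checks (e.g. verifying the closed-form
#' `tau` against the empirical correlation of `P` and `F`, or testing the
#' combined statistic against N(0, 1)); it applies the same formulas as
#' [popfam_test()] through the exported vectorized statistic functions.
#'
#' @param n_reps Number of independent null replicates.
#' @param maf Marker minor-allele frequency.
#' @param n_trios,n_controls Per-replicate sample sizes.
#' @param variance `"hwe"` or `"mom"`.
#' @param w Fixed weight for the combined statistic (default 1/2).
#' @return A tibble with one row per replicate: `P`, `F` (NA when
#'   `H = 0`), `H`, `T_sum`, `sigma2`, `maf_hat`, `tau`, `z`.
#' @export
#' @examples
#' set.seed(1)
#' s <- simulate_null_stats(1000, maf = 0.2, n_trios = 50, n_controls = 50)
#' cor(s$P, s$F)
simulate_null_stats <- function(n_reps, maf, n_trios, n_controls,
                                variance = c("hwe", "mom"), w = 0.5) {
  variance <- match.arg(variance)
  if (maf <= 0 || maf >= 1) abort("`maf` must be strictly inside (0, 1).")
  n <- n_trios
  m <- n_controls
  fg <- matrix(rbinom(n_reps * n, 2L, maf), nrow = n_reps)
  mg <- matrix(rbinom(n_reps * n, 2L, maf), nrow = n_reps)
  tf <- (fg == 2L) + (fg == 1L) * matrix(
    rbinom(n_reps * n, 1L, 0.5), nrow = n_reps
  )
  tm <- (mg == 2L) + (mg == 1L) * matrix(
    rbinom(n_reps * n, 1L, 0.5), nrow = n_reps
  )
  child <- tf + tm
  het_f <- fg == 1L
  het_m <- mg == 1L
  h_tot <- rowSums(het_f) + rowSums(het_m)
  t_sum <- rowSums(het_f * tf) + rowSums(het_m * tm)
  ctrl <- matrix(rbinom(n_reps * m, 2L, maf), nrow = n_reps)

  case_sum <- rowSums(child)
  ctrl_sum <- rowSums(ctrl)
  maf_hat <- (case_sum + ctrl_sum) / (2 * (n + m))
  sigma2 <- if (variance == "hwe") {
    sigma2_hwe(maf_hat)
  } else {
    g1 <- rowSums(child == 1L) + rowSums(ctrl == 1L)
    g2 <- rowSums(child == 2L) + rowSums(ctrl == 2L)
    sigma2_mom(g1, g2, n + m)
  }
  ok_p <- sigma2 > 0
  p_stat <- rep(NA_real_, n_reps)
  p_stat[ok_p] <- (case_sum[ok_p] / n - ctrl_sum[ok_p] / m) /
    sqrt(sigma2[ok_p] * (1 / n + 1 / m))

  f_stat <- rep(NA_real_, n_reps)
  ok_f <- h_tot >= 1L
  f_stat[ok_f] <- wald_stat(h_tot[ok_f], t_sum[ok_f])

  tau <- rep(0, n_reps)
  both <- ok_p & ok_f
  tau[both] <- compute_tau(n, m, h_tot[both], sigma2[both])

  z <- rep(NA_real_, n_reps)
  z[both] <- popfam_stat(p_stat[both], f_stat[both], w, tau[both])
  z[ok_p & !ok_f] <- p_stat[ok_p & !ok_f]   # trend-only fallback
  z[!ok_p & ok_f] <- f_stat[!ok_p & ok_f]

  tibble(
    P = p_stat, F = f_stat, H = h_tot, T_sum = t_sum,
    sigma2 = sigma2, maf_hat = maf_hat, tau = tau, z = z
  )
}
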