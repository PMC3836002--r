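#' Two-locus penetrance model for simulation
#'
#' Parameterizes the disease architecture used by the conditional genotype
#' simulator: a biallelic disease locus with risk-allele frequency `daf`
#' and penetrances `f0 <= f1 <= f2` (probability of being affected given
#' 0, 1 or 2 risk alleles; `f0` is the phenocopy rate), observed through a
#' linked biallelic marker with minor-allele frequency `marker_maf` and
#' linkage disequilibrium `dprime` with the risk allele.
#'
#' @param daf Disease (risk) allele frequency, in (0, 1).
#' @param f1,f2 Penetrances of the heterozygote and risk homozygote.
#' @param f0 Penetrance of the wildtype homozygote (phenocopy rate);
#'   default 0.045.
#' @param marker_maf Marker minor-allele frequency; defaults to `daf`.
#' @param dprime Standardized LD coefficient D' between the marker minor
#'   allele and the risk allele, in `[0, 1]` (positive coupling: the minor
#'   allele tags the risk allele).
#' @return An object of class `genetic_model`.
#' @export
#' @examples
#' m <- genetic_model(daf = 0.03, f1 = 0.125, f2 = 0.440)
#' prevalence(m)
genetic_model <- function(daf, f1, f2, f0 = 0.045, marker_maf = daf,
                          dprime = 0.8) {
  if (daf <= 0 || daf >= 1) abort("`daf` must be strictly inside (0, 1).")
  if (marker_maf <= 0 || marker_maf >= 1) {
    abort("`marker_maf` must be strictly inside (0, 1).")
  }
  if (dprime < 0 || dprime > 1) abort("`dprime` must lie in [0, 1].")
  for (f in c(f0, f1, f2)) {
    if (f < 0 || f > 1) abort("penetrances must lie in [0, 1].")
  }
  structure(
    list(
      daf = daf, f0 = f0, f1 = f1, f2 = f2,
      marker_maf = marker_maf, dprime = dprime
    ),
    class = "genetic_model"
  )
}

#' @export
print.genetic_model <- function(x, ...) {
  cat("<genetic_model> DAF = ", x$daf, ", penetrances (f0, f1, f2) = (",
    x$f0, ", ", x$f1, ", ", x$f2, "), marker MAF = ", x$marker_maf,
    ", D' = ", x$dprime, "\n",
    sep = ""
  )
  cat("  implied prevalence K = ", format(prevalence(x), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Population disease prevalence implied by a penetrance model
#'
#' Closed form under HWE at the disease locus:
#' `K = f0 * (1-p)^2 + f1 * 2p(1-p) + f2 * p^2` with `p = daf`.
#'
#' @param model A [genetic_model].
#' @return The prevalence `K` in (0, 1).
#' @export
prevalence <- function(model) {
  stopifnot(inherits(model, "genetic_model"))
  p <- model$daf
  model$f0 * (1 - p)^2 + model$f1 * 2 * p * (1 - p) + model$f2 * p^2
}

#' Marker-disease haplotype frequencies from allele frequencies and D'
#'
#' Builds the four haplotype frequencies of a (marker, disease) locus pair
#' from the marginal allele frequencies and the standardized LD
#' coefficient: `D = dprime * Dmax` with
#' `Dmax = min(marker_maf * (1 - daf), (1 - marker_maf) * daf)`, coupling
#' the marker minor allele positively with the risk allele
#' (`q11 = marker_maf * daf + D`); the other cells follow by margin
#' subtraction.
#'
#' @param marker_maf,daf Marginal frequencies of the marker minor allele
#'   and the risk allele, in (0, 1).
#' @param dprime Standardized LD, in `[0, 1]`.
#' @return A four-row tibble with columns `marker` (1/0 minor allele),
#'   `disease` (1/0 risk allele) and `freq`; frequencies sum to 1 and
#'   reproduce the margins.
#' @export
#' @examples
#' haplotype_freqs(marker_maf = 0.2, daf = 0.2, dprime = 1)
haplotype_freqs <- function(marker_maf, daf, dprime) {
  q <- hap_probs(marker_maf, daf, dprime)
  tibble(
    marker = c(1L, 1L, 0L, 0L),
    disease = c(1L, 0L, 1L, 0L),
    freq = q
  )
}

# haplotype probabilities as a bare vector (q11, q10, q01, q00)
hap_probs <- function(marker_maf, daf, dprime) {
  if (marker_maf <= 0 || marker_maf >= 1 || daf <= 0 || daf >= 1) {
    abort("allele frequencies must be strictly inside (0, 1).")
  }
  if (dprime < 0 || dprime > 1) abort("`dprime` must lie in [0, 1].")
  dmax <- min(marker_maf * (1 - daf), (1 - marker_maf) * daf)
  d <- dprime * dmax
  q <- c(
    marker_maf * daf + d,
    marker_maf * (1 - daf) - d,
    (1 - marker_maf) * daf - d,
    (1 - marker_maf) * (1 - daf) + d
  )
  if (any(q < -1e-12)) abort("negative haplotype frequency cell.")
  pmax(q, 0)
}

#' Simulation scenarios for the power study
#'
#' The six alternative-hypothesis genetic models of the power study: disease
#' allele frequency from 0.03 to 0.30 with marker MAF equal to the DAF,
#' penetrances tuned so that every scenario implies a population prevalence
#' of 5% with a 4.5% phenocopy rate, and D' = 0.80 between marker and risk
#' allele.
#'
#' @return A tibble with columns `scenario`, `daf`, `marker_maf`, `f0`,
#'   `f1`, `f2`, `dprime`.
#' @export
#' @examples
#' popfam_scenarios()
popfam_scenarios <- function() {
  tibble(
    scenario = paste0("S", 1:6),
    daf = c(0.03, 0.06, 0.09, 0.12, 0.20, 0.30),
    marker_maf = c(0.03, 0.06, 0.09, 0.12, 0.20, 0.30),
    f0 = 0.045,
    f1 = c(0.125, 0.084, 0.066, 0.060, 0.053, 0.050),
    f2 = c(0.440, 0.218, 0.237, 0.173, 0.100, 0.080),
    dprime = 0.8
  )
}

#' Look up one scenario as a genetic model
#'
#' @param scenario Scenario label, `"S1"` to `"S6"`.
#' @return A [genetic_model].
#' @export
scenario_model <- function(scenario) {
  sc <- popfam_scenarios()
  row <- sc[sc$scenario == scenario, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown scenario '", scenario, "' (use S1..S6)."))
  }
  genetic_model(
    daf = row$daf, f1 = row$f1, f2 = row$f2, f0 = row$f0,
    marker_maf = row$marker_maf, dprime = row$dprime
  )
}
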