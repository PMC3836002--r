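#' Bundle trios and controls into a mixed dataset
#'
#' The unit on which [popfam_test()] runs: `N` case-parent trios (the
#' affected offspring double as the cases of the population-based
#' component) together with `M` unrelated controls, at one biallelic
#' marker coded as minor-allele counts.
#'
#' @param trios Data frame with columns `father_g`, `mother_g`, `child_g`
#'   (values 0, 1, 2 or `NA` for missing).
#' @param controls Integer vector of control minor-allele counts, or a data
#'   frame with a column `g`. `NA` entries are dropped with a message.
#' @param inconsistent Policy for Mendelian-inconsistent trios, passed to
#'   [add_transmissions()]: `"drop"` (default) or `"error"`.
#' @return An object of class `mixed_data`: a list with tibbles `trios`
#'   (annotated with `h`, `t`) and `controls`, plus the count of dropped
#'   inconsistent trios.
#' @export
#' @examples
#' md <- mixed_data(
#'   trios = tibble::tibble(father_g = c(1, 2), mother_g = c(0, 1),
#'                          child_g = c(1, 2)),
#'   controls = c(0, 1, 0)
#' )
#' md
mixed_data <- function(trios, controls, inconsistent = c("drop", "error")) {
  inconsistent <- match.arg(inconsistent)
  trios <- add_transmissions(trios, inconsistent = inconsistent)
  n_dropped <- attr(trios, "n_dropped") %||% 0L
  if (is.data.frame(controls)) {
    if (!"g" %in% names(controls)) abort("`controls` data frame needs a `g` column.")
    controls <- controls$g
  }
  controls <- as.integer(controls)
  if (anyNA(controls)) {
    inform(paste0("dropping ", sum(is.na(controls)),
                  " control(s) with missing genotype."))
    controls <- controls[!is.na(controls)]
  }
  if (!all(controls %in% 0:2)) {
    abort("control genotypes must be allele counts 0, 1 or 2.")
  }
  if (nrow(trios) == 0 && length(controls) == 0) {
    abort("empty dataset: no trios and no controls.", class = "popfam_empty")
  }
  structure(
    list(
      trios = as_tibble(trios),
      controls = tibble(g = controls),
      n_dropped = as.integer(n_dropped)
    ),
    class = "mixed_data"
  )
}

#' @export
print.mixed_data <- function(x, ...) {
  cts <- md_counts(x)
  cat("<mixed_data> ", cts$N, " case-parent trios, ", cts$M, " controls\n",
    "  heterozygous parents H = ", cts$H, " (", cts$X,
    " informative trios), transmitted minor alleles T = ", cts$T_sum, "\n",
    "  pooled minor allele frequency = ",
    format(cts$maf_hat, digits = 3), "\n",
    sep = ""
  )
  invisible(x)
}

# Summary counts used throughout: N cases (genotyped offspring), M controls,
# H heterozygous parents and T transmitted minor alleles over complete trios,
# X trios with at least one heterozygous parent, pooled genotype counts.
md_counts <- function(x) {
  stopifnot(inherits(x, "mixed_data"))
  case_g <- x$trios$child_g[!is.na(x$trios$child_g)]
  ctrl_g <- x$controls$g
  ok <- !is.na(x$trios$h)
  pooled <- c(case_g, ctrl_g)
  list(
    N = length(case_g),
    M = length(ctrl_g),
    H = sum(x$trios$h[ok]),
    X = sum(x$trios$h[ok] >= 1L),
    T_sum = sum(x$trios$t[ok]),
    g1 = sum(pooled == 1L),
    g2 = sum(pooled == 2L),
    maf_hat = if (length(pooled)) mean(pooled) / 2 else NA_real_,
    case_g = case_g,
    control_g = ctrl_g
  )
}
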