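#' POPFAM combined test of association
#'
#' Runs the combined family- and population-based test on a mixed dataset:
#' the trend statistic `P` contrasts the trio offspring (cases) with the
#' controls on mean minor-allele count, the Wald statistic `F` measures
#' excess transmission of the minor allele from heterozygous parents, and
#' the two are linearly combined with weight `w` and rescaled by their
#' closed-form null covariance `tau` so the result is N(0, 1) under no
#' association. The reported p-value is two-sided.
#'
#' Degenerate inputs degrade gracefully: with no heterozygous parents
#' (`H = 0`) the family component carries no information and the test
#' reduces to `P` alone (`w = 1`, `tau = 0`); at a marker monomorphic in
#' the pooled case-control sample the test reduces to `F` alone when
#' `H >= 1` and errors otherwise.
#'
#' @param data A [mixed_data] object, or a trio data frame (columns
#'   `father_g`, `mother_g`, `child_g`) combined with `controls`.
#' @param controls Control allele counts, only used when `data` is a plain
#'   trio data frame.
#' @param variance `"hwe"` (default) or `"mom"`; see [trend_stat()].
#' @param weight `"half"` fixes `w = 1/2` (appropriate when the component
#'   tests have comparable power, e.g. equal numbers of cases and
#'   controls); `"sample_size"` uses [compute_weight()] with the observed
#'   `H`. A numeric `w` overrides both.
#' @param w Optional fixed numeric weight in `[0, 1]`.
#' @param p0 Null transmission probability for the Wald component.
#' @param inconsistent Mendelian-inconsistency policy when `data` is a
#'   plain data frame; see [mixed_data()].
#' @return An object of class `popfam_test` with the combined statistic
#'   (`statistic`), `p.value`, components `P` and `F`, `w`, `tau`,
#'   `sigma2`, `maf_hat`, the counts `N`, `M`, `H`, `X`, `T_sum`, and any
#'   `flags`. [tidy()] returns it as a one-row tibble.
#' @export
#' @examples
#' set.seed(1)
#' md <- simulate_null_data(maf = 0.2, n_trios = 100, n_controls = 100)
#' fit <- popfam_test(md)
#' tidy(fit)
popfam_test <- function(data, controls = NULL,
                        variance = c("hwe", "mom"),
                        weight = c("half", "sample_size"),
                        w = NULL, p0 = 0.5,
                        inconsistent = c("drop", "error")) {
  variance <- match.arg(variance)
  if (is.numeric(weight)) {
    w <- weight
    weight <- "fixed"
  } else {
    weight <- match.arg(weight)
  }
  if (!inherits(data, "mixed_data")) {
    data <- mixed_data(data, controls, inconsistent = match.arg(inconsistent))
  }
  cts <- md_counts(data)
  flags <- character(0)
  if (data$n_dropped > 0) {
    flags <- c(flags, paste0("mendelian_drops:", data$n_dropped))
  }

  polymorphic <- cts$N >= 1 && cts$M >= 1 &&
    cts$maf_hat > 0 && cts$maf_hat < 1
  if (!polymorphic && cts$H < 1) {
    abort("marker is monomorphic and has no informative transmissions.",
      class = "popfam_degenerate"
    )
  }

  p_stat <- NA_real_
  f_stat <- NA_real_
  sigma2 <- NA_real_
  tau <- 0

  if (polymorphic) {
    tr <- trend_stat(cts$case_g, cts$control_g, variance = variance)
    p_stat <- tr$P
    sigma2 <- tr$sigma2
  } else {
    flags <- c(flags, "monomorphic")
  }
  if (cts$H >= 1) {
    f_stat <- wald_stat(cts$H, cts$T_sum, p0 = p0)
  }

  if (!polymorphic) {
    # F alone: no trend component at a monomorphic marker
    w_used <- 0
    z <- f_stat
  } else if (cts$H < 1) {
    # no informative transmissions: trend test alone
    flags <- c(flags, "H0_fallback")
    w_used <- 1
    z <- p_stat
  } else {
    w_used <- if (!is.null(w)) {
      w
    } else if (weight == "half") {
      0.5
    } else {
      compute_weight(cts$N, cts$M, cts$H)
    }
    tau <- compute_tau(cts$N, cts$M, cts$H, sigma2)
    z <- popfam_stat(p_stat, f_stat, w_used, tau)
  }

  structure(
    list(
      statistic = z,
      p.value = 2 * pnorm(-abs(z)),
      P = p_stat, F = f_stat,
      w = w_used, tau = tau,
      sigma2 = sigma2, maf_hat = cts$maf_hat,
      N = cts$N, M = cts$M, H = cts$H, X = cts$X, T_sum = cts$T_sum,
      variance = variance, weight_mode = weight, p0 = p0,
      flags = flags
    ),
    class = "popfam_test"
  )
}

#' @export
print.popfam_test <- function(x, digits = 4, ...) {
  cat("\n\tPOPFAM combined test of association\n\n")
  cat("data: ", x$N, " case-parent trios, ", x$M, " controls (H = ", x$H,
    ", T = ", x$T_sum, ")\n",
    sep = ""
  )
  cat("z = ", format(x$statistic, digits = digits),
    ", two-sided p-value = ", format(x$p.value, digits = digits), "\n",
    sep = ""
  )
  cat("components: P = ", format(x$P, digits = digits),
    ", F = ", format(x$F, digits = digits),
    "  (w = ", format(x$w, digits = digits),
    ", tau = ", format(x$tau, digits = digits), ")\n",
    sep = ""
  )
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a POPFAM test result
#'
#' @param x A `popfam_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the statistics, weight, covariance,
#'   p-value and the counts behind them.
#' @method tidy popfam_test
#' @export
tidy.popfam_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, p.value = x$p.value,
    P = x$P, F = x$F, w = x$w, tau = x$tau,
    maf_hat = x$maf_hat, sigma2 = x$sigma2,
    N = x$N, M = x$M, H = x$H, X = x$X, T_sum = x$T_sum,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Model-level summary of a POPFAM test
#'
#' @param x A `popfam_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the dataset counts, variance mode and
#'   weighting used.
#' @method glance popfam_test
#' @export
glance.popfam_test <- function(x, ...) {
  tibble(
    N = x$N, M = x$M, H = x$H, X = x$X,
    maf_hat = x$maf_hat, sigma2 = x$sigma2,
    variance = x$variance, weight_mode = x$weight_mode,
    statistic = x$statistic, p.value = x$p.value
  )
}
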