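#' Per-marker association scan
#'
#' Runs [popfam_test()] on every marker of a cohort and collects the
#' results as one tidy table. Degenerate markers (monomorphic with no
#' informative transmissions, or otherwise failing) become flagged rows
#' with missing statistics; the scan never aborts on a single marker.
#'
#' @param cohort A `popfam_cohort` from [read_ped()], or a named list of
#'   [mixed_data] objects.
#' @param variance,weight,w,p0 Passed to [popfam_test()].
#' @param adjust If `TRUE`, append a Benjamini-Hochberg adjusted p-value
#'   column `p_adj` (off by default).
#' @return A tibble with one row per marker: `marker`, counts `N`, `M`,
#'   `H`, `X`, `maf_hat`, statistics `P`, `F`, `w`, `tau`, `z`, `p_value`
#'   and semicolon-separated `flags`.
#' @export
#' @examples
#' set.seed(2)
#' md <- simulate_null_data(0.3, 50, 50)
#' assoc_scan(list(SNP1 = md))
assoc_scan <- function(cohort, variance = c("hwe", "mom"),
                       weight = c("half", "sample_size"), w = NULL,
                       p0 = 0.5, adjust = FALSE) {
  data <- if (inherits(cohort, "popfam_cohort")) cohort$data else cohort
  if (is.null(names(data))) names(data) <- paste0("M", seq_along(data))
  out <- purrr::imap(data, function(d, id) {
    res <- tryCatch(
      popfam_test(d, variance = variance, weight = weight, w = w, p0 = p0),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      cts <- tryCatch(md_counts(d), error = function(e) NULL)
      return(tibble(
        marker = id,
        N = cts$N %||% NA_integer_, M = cts$M %||% NA_integer_,
        H = cts$H %||% NA_integer_, X = cts$X %||% NA_integer_,
        maf_hat = cts$maf_hat %||% NA_real_,
        P = NA_real_, F = NA_real_, w = NA_real_, tau = NA_real_,
        z = NA_real_, p_value = NA_real_,
        flags = paste0("error:", conditionMessage(res))
      ))
    }
    tibble(
      marker = id,
      N = res$N, M = res$M, H = res$H, X = res$X, maf_hat = res$maf_hat,
      P = res$P, F = res$F, w = res$w, tau = res$tau,
      z = res$statistic, p_value = res$p.value,
      flags = paste(res$flags, collapse = ";")
    )
  })
  out <- dplyr::bind_rows(out)
  if (adjust) out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}

#' QQ plot of association scan p-values
#'
#' Observed versus expected -log10 p-values across markers, with the
#' identity line; the standard diagnostic for an association scan.
#'
#' @param assoc An association table from [assoc_scan()].
#' @return A ggplot object.
#' @export
plot_qq <- function(assoc) {
  p <- sort(assoc$p_value[!is.na(assoc$p_value)])
  df <- tibble(
    expected = -log10(stats::ppoints(length(p))),
    observed = -log10(p)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "expected -log10(p)", y = "observed -log10(p)"
    ) +
    ggplot2::theme_minimal()
}
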