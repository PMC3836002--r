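#' Configuration for a type-I-error or power study
#'
#' Bundles the study conditions: the genetic scenarios, the sample sizes
#' (200 trios and 200 controls by default), the number of replicates, the
#' significance levels, the weighting and variance modes of the combined
#' test, the control sampling mode and the base seed. Replicate `r` of
#' scenario `i` is run with seed `base_seed + (i - 1) * n_reps + r`, so
#' results are identical whether replicates are executed serially or
#' concurrently.
#'
#' @param scenarios A tibble of scenarios as returned by
#'   [popfam_scenarios()] (any subset of its rows, or a compatible tibble).
#' @param n_trios,n_controls Per-replicate sample sizes.
#' @param n_reps Number of replicates per scenario.
#' @param alphas Two-sided significance levels, each in (0, 1].
#' @param weight `"half"`, `"sample_size"`, or a fixed numeric weight.
#' @param variance `"hwe"` or `"mom"`.
#' @param controls_mode `"unaffected"` or `"population"`.
#' @param base_seed Integer base seed.
#' @return An object of class `power_config`.
#' @export
power_config <- function(scenarios = popfam_scenarios(),
                         n_trios = 200, n_controls = 200,
                         n_reps = 1000, alphas = c(0.05, 0.01),
                         weight = "half", variance = c("hwe", "mom"),
                         controls_mode = c("unaffected", "population"),
                         base_seed = 1L) {
  variance <- match.arg(variance)
  controls_mode <- match.arg(controls_mode)
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  if (any(alphas <= 0 | alphas > 1)) abort("`alphas` must lie in (0, 1].")
  structure(
    list(
      scenarios = as_tibble(scenarios),
      n_trios = n_trios, n_controls = n_controls,
      n_reps = as.integer(n_reps), alphas = alphas,
      weight = weight, variance = variance,
      controls_mode = controls_mode, base_seed = as.integer(base_seed)
    ),
    class = "power_config"
  )
}

# run popfam_test on one dataset and pull the three statistics
component_stats <- function(data, config) {
  fit <- popfam_test(data,
    variance = config$variance, weight = config$weight
  )
  c(z = fit$statistic, P = fit$P, F = fit$F)
}

# turn a reps x 3 matrix of statistics into the tidy rejection table
tally_rejections <- function(stats, config, scenario, maf) {
  methods <- c(POPFAM = "z", P = "P", F = "F")
  rows <- purrr::map_dfr(names(methods), function(meth) {
    vals <- stats[, methods[[meth]]]
    used <- !is.na(vals)
    purrr::map_dfr(config$alphas, function(a) {
      crit <- qnorm(1 - a / 2)
      rej <- sum(abs(vals[used]) >= crit)
      rate <- rej / sum(used)
      tibble(
        scenario = scenario, maf = maf, method = meth, alpha = a,
        n_reps = config$n_reps, n_used = sum(used),
        rejections = rej, rate = rate,
        mc_se = sqrt(rate * (1 - rate) / sum(used))
      )
    })
  })
  rows
}

as_popfam_study <- function(x, config, type) {
  structure(
    x,
    config = config, study_type = type,
    class = c("popfam_study", class(x))
  )
}

#' Empirical type I error of the combined test and its components
#'
#' For each replicate, simulates a null mixed dataset
#' ([simulate_null_data()]), runs [popfam_test()], and records two-sided
#' rejections of the combined statistic and of the standalone `P` and `F`
#' components (each referred to N(0, 1)) at every significance level.
#' Replicates where `H = 0` contribute no `F` rejection and are excluded
#' from its denominator (`n_used`).
#'
#' @param config A [power_config].
#' @param maf Marker MAF of the null simulations (default 0.2).
#' @return A `popfam_study` tibble with one row per (method, alpha):
#'   rejection counts, rates and Monte-Carlo standard errors.
#' @export
#' @examples
#' cfg <- power_config(n_reps = 50, n_trios = 50, n_controls = 50)
#' run_type1(cfg, maf = 0.2)
run_type1 <- function(config, maf = 0.2) {
  stopifnot(inherits(config, "power_config"))
  stats <- matrix(NA_real_, nrow = config$n_reps, ncol = 3,
    dimnames = list(NULL, c("z", "P", "F"))
  )
  for (r in seq_len(config$n_reps)) {
    set.seed(config$base_seed + r)
    d <- simulate_null_data(maf, config$n_trios, config$n_controls)
    stats[r, ] <- component_stats(d, config)
  }
  out <- tally_rejections(stats, config, scenario = "null", maf = maf)
  as_popfam_study(out, config, "type1")
}

#' Empirical power of the combined test and its components
#'
#' As [run_type1()], but each replicate draws an ascertained dataset under
#' the scenario's genetic model ([simulate_alt_data()]). One block of
#' replicates per scenario row of the configuration.
#'
#' @param config A [power_config].
#' @return A `popfam_study` tibble with one row per
#'   (scenario, method, alpha).
#' @export
#' @examples
#' cfg <- power_config(
#'   scenarios = popfam_scenarios()[1, ],
#'   n_reps = 20, n_trios = 50, n_controls = 50
#' )
#' run_power(cfg)
run_power <- function(config) {
  stopifnot(inherits(config, "power_config"))
  sc <- config$scenarios
  out <- purrr::map_dfr(seq_len(nrow(sc)), function(i) {
    model <- genetic_model(
      daf = sc$daf[i], f1 = sc$f1[i], f2 = sc$f2[i], f0 = sc$f0[i],
      marker_maf = sc$marker_maf[i], dprime = sc$dprime[i]
    )
    stats <- matrix(NA_real_, nrow = config$n_reps, ncol = 3,
      dimnames = list(NULL, c("z", "P", "F"))
    )
    for (r in seq_len(config$n_reps)) {
      set.seed(config$base_seed + (i - 1L) * config$n_reps + r)
      d <- simulate_alt_data(model, config$n_trios, config$n_controls,
        controls_mode = config$controls_mode
      )
      stats[r, ] <- component_stats(d, config)
    }
    tally_rejections(stats, config, scenario = sc$scenario[i], maf = sc$daf[i])
  })
  as_popfam_study(out, config, "power")
}

#' Format a study result as a fixed-layout table
#'
#' Renders rejection rates scenario-by-method: power studies as percent
#' with one decimal, type-I-error studies as proportions with three
#' decimals, each with its Monte-Carlo standard error.
#'
#' @param results A `popfam_study` tibble from [run_type1()] or
#'   [run_power()].
#' @param alpha Which significance level to tabulate (default the smallest
#'   study alpha >= 0.05, else the first).
#' @param file Optional path: the tidy results are also written as TSV
#'   (see [write_study()]).
#' @return The formatted table as a character vector of lines (invisibly
#'   printed with `cat()` when interactive callers want it, returned for
#'   programmatic use).
#' @export
report_tables <- function(results, alpha = NULL, file = NULL) {
  type <- attr(results, "study_type") %||% "power"
  if (!is.null(file)) write_study(results, file)
  if (nrow(results) == 0) {
    return(c("scenario\tPOPFAM\tP\tF"))
  }
  alpha <- alpha %||% {
    a <- sort(unique(results$alpha), decreasing = TRUE)
    a[[1]]
  }
  sub <- results[results$alpha == alpha, , drop = FALSE]
  fmt <- function(rate, se) {
    if (type == "power") {
      sprintf("%.1f (%.1f)", 100 * rate, 100 * se)
    } else {
      sprintf("%.3f (%.3f)", rate, se)
    }
  }
  wide <- sub |>
    mutate(cell = fmt(.data$rate, .data$mc_se)) |>
    select("scenario", "method", "cell") |>
    tidyr::pivot_wider(names_from = "method", values_from = "cell")
  header <- paste(
    c("scenario", setdiff(names(wide), "scenario")),
    collapse = "\t"
  )
  unit <- if (type == "power") "% (MC SE)" else "proportion (MC SE)"
  body <- apply(wide, 1, paste, collapse = "\t")
  c(paste0("# rejection rate at alpha = ", alpha, ", ", unit), header, body)
}

#' Write / read a study result as TSV
#'
#' `write_study()` stores the tidy replicate summaries; `read_study()`
#' restores them (numeric columns typed, class reattached) so that a
#' round-trip reproduces the in-memory results.
#'
#' @param results A `popfam_study` tibble.
#' @param file Path to a TSV file.
#' @return `read_study()` returns a `popfam_study` tibble;
#'   `write_study()` returns `file` invisibly.
#' @export
write_study <- function(results, file) {
  readr::write_tsv(as_tibble(results), file)
  invisible(file)
}

#' @rdname write_study
#' @export
read_study <- function(file) {
  out <- readr::read_tsv(
    file,
    col_types = readr::cols(
      scenario = readr::col_character(),
      method = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  structure(out, class = c("popfam_study", class(out)))
}

#' Plot rejection rates of a study
#'
#' Power (or type I error) per scenario and method with +-2 MC SE error
#' bars, at one significance level.
#'
#' @param object A `popfam_study` tibble.
#' @param alpha Significance level to plot (default: largest in the study).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot popfam_study
#' @export
autoplot.popfam_study <- function(object, alpha = NULL, ...) {
  alpha <- alpha %||% max(object$alpha)
  sub <- object[object$alpha == alpha, , drop = FALSE]
  ggplot2::ggplot(
    sub,
    ggplot2::aes(
      x = .data$scenario, y = .data$rate,
      colour = .data$method, group = .data$method
    )
  ) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(.data$rate - 2 * .data$mc_se, 0),
        ymax = pmin(.data$rate + 2 * .data$mc_se, 1)
      ),
      width = 0.2, position = ggplot2::position_dodge(width = 0.3)
    ) +
    ggplot2::labs(
      y = paste0("rejection rate at alpha = ", alpha),
      x = "scenario", colour = "test"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.popfam_study
#' @param results A `popfam_study` tibble.
#' @export
plot_power <- function(results, alpha = NULL) {
  autoplot.popfam_study(results, alpha = alpha)
}
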