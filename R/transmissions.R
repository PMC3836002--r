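#' Count informative transmissions in a case-parent trio
#'
#' For each trio, `h` is the number of heterozygous parents (the only
#' parents informative for transmission) and `t` the number of minor ("1")
#' alleles the affected offspring received from heterozygous parents. Since
#' each homozygous 1/1 parent transmits exactly one minor allele and each
#' 0/0 parent none, `t = child_g - #(parents with genotype 2)` and is
#' uniquely determined by the three genotypes (no phasing needed).
#'
#' @param father_g,mother_g,child_g Minor-allele counts (0, 1 or 2).
#'   Vectorized; recycled to a common length.
#' @return A tibble with integer columns `h` and `t`, one row per trio.
#'   `0 <= t <= h` always holds for Mendelian-consistent trios.
#' @details A trio for which `t` would fall outside `[0, h]` (for example
#'   both parents 0/0 but the child carrying a minor allele) is
#'   Mendelian-inconsistent and raises an error of class
#'   `popfam_mendel_error`. Use [add_transmissions()] for a
#'   drop-with-warning policy over a table of trios.
#' @export
#' @examples
#' count_transmissions(1, 0, 1)
count_transmissions <- function(father_g, mother_g, child_g) {
  n <- max(length(father_g), length(mother_g), length(child_g))
  father_g <- rep_len(as.integer(father_g), n)
  mother_g <- rep_len(as.integer(mother_g), n)
  child_g <- rep_len(as.integer(child_g), n)
  for (g in list(father_g, mother_g, child_g)) {
    if (anyNA(g) || !all(g %in% 0:2)) {
      abort("genotypes must be allele counts 0, 1 or 2 (no missing values).")
    }
  }
  h <- (father_g == 1L) + (mother_g == 1L)
  t <- child_g - ((father_g == 2L) + (mother_g == 2L))
  bad <- t < 0L | t > h
  if (any(bad)) {
    abort(
      paste0(
        "Mendelian-inconsistent trio(s) at position(s) ",
        paste(head(which(bad), 5), collapse = ", "),
        ": child genotype impossible given the parents."
      ),
      class = "popfam_mendel_error"
    )
  }
  tibble(h = as.integer(h), t = as.integer(t))
}

#' Annotate a trio table with transmission counts
#'
#' Adds `h` (heterozygous-parent count) and `t` (transmitted minor alleles
#' from heterozygous parents) columns to a data frame of trio genotypes.
#' Trios with a missing genotype get `h = t = NA` and contribute nothing to
#' the family-based statistic downstream.
#'
#' @param trios A data frame with columns `father_g`, `mother_g`, `child_g`.
#' @param inconsistent Policy for Mendelian-inconsistent trios: `"drop"`
#'   removes them with a warning, `"error"` aborts.
#' @return A tibble: the input rows (minus any dropped) with `h` and `t`
#'   appended; the number of dropped trios is recorded in attribute
#'   `n_dropped`.
#' @export
add_transmissions <- function(trios, inconsistent = c("drop", "error")) {
  inconsistent <- match.arg(inconsistent)
  trios <- as_tibble(trios)
  need <- c("father_g", "mother_g", "child_g")
  if (!all(need %in% names(trios))) {
    abort("`trios` needs columns father_g, mother_g and child_g.")
  }
  complete <- !is.na(trios$father_g) & !is.na(trios$mother_g) &
    !is.na(trios$child_g)
  h <- rep(NA_integer_, nrow(trios))
  t <- rep(NA_integer_, nrow(trios))
  drop <- rep(FALSE, nrow(trios))
  if (any(complete)) {
    fg <- as.integer(trios$father_g[complete])
    mg <- as.integer(trios$mother_g[complete])
    cg <- as.integer(trios$child_g[complete])
    if (!all(c(fg, mg, cg) %in% 0:2)) {
      abort("genotypes must be allele counts 0, 1 or 2.")
    }
    hh <- (fg == 1L) + (mg == 1L)
    tt <- cg - ((fg == 2L) + (mg == 2L))
    bad <- tt < 0L | tt > hh
    if (any(bad)) {
      if (inconsistent == "error") {
        abort(
          paste0(sum(bad), " Mendelian-inconsistent trio(s) found."),
          class = "popfam_mendel_error"
        )
      }
      warn(paste0("dropping ", sum(bad), " Mendelian-inconsistent trio(s)."))
      drop[complete][bad] <- TRUE
    }
    h[complete] <- as.integer(hh)
    t[complete] <- as.integer(tt)
  }
  out <- trios
  out$h <- h
  out$t <- t
  out <- out[!drop, , drop = FALSE]
  attr(out, "n_dropped") <- sum(drop)
  out
}
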