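# PED/MAP text dialect: classic whitespace-delimited linkage pedigree files.
# PED: family id, individual id, father id, mother id, sex, phenotype
# (0/-9 missing, 1 unaffected, 2 affected), then one allele pair per
# marker; allele codes 1/2 or A/C/G/T, 0 = missing. MAP: chromosome,
# marker id, genetic distance, physical position (metadata only).

#' Read a PED/MAP cohort into per-marker mixed datasets
#'
#' Parses a pedigree file, resolves case-parent trios (affected offspring
#' whose father and mother are both present in the same family), classifies
#' unaffected founders that are nobody's parent as unrelated controls, and
#' recodes every marker as counts of its minor allele (the rarer allele in
#' the pooled sample; ties broken by allele-code order). Unaffected
#' non-founders contribute to neither component and are reported via a
#' message.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return An object of class `popfam_cohort`: a list with `markers` (a
#'   tibble of MAP metadata plus the minor/major allele codes) and `data`
#'   (a named list of [mixed_data], one per marker, in MAP order).
#' @export
read_ped <- function(ped_path, map_path) {
  map <- utils::read.table(
    map_path,
    header = FALSE, colClasses = "character",
    col.names = c("chrom", "id", "cm", "pos")
  )
  map <- as_tibble(map)
  if (anyDuplicated(map$id)) abort("duplicate marker ids in MAP file.")
  n_mark <- nrow(map)

  raw <- readLines(ped_path)
  raw <- raw[nzchar(trimws(raw))]
  fields <- strsplit(trimws(raw), "[ \t]+")
  want <- 6 + 2 * n_mark
  bad <- which(lengths(fields) != want)
  if (length(bad)) {
    abort(paste0(
      "malformed PED line ", bad[1], ": expected ", want,
      " fields, found ", lengths(fields)[bad[1]], "."
    ))
  }
  ped <- do.call(rbind, fields)
  ind <- tibble(
    fid = ped[, 1], iid = ped[, 2], pid = ped[, 3], mid = ped[, 4],
    sex = ped[, 5], pheno = ped[, 6]
  )
  if (anyDuplicated(paste(ind$fid, ind$iid))) {
    abort("duplicate individual (family id, individual id) in PED file.")
  }

  alleles <- ped[, -(1:6), drop = FALSE]
  valid_codes <- c("0", "1", "2", "A", "C", "G", "T")
  if (!all(alleles %in% valid_codes)) {
    abort("invalid allele code in PED file (allowed: 0, 1, 2, A, C, G, T).")
  }

  key <- paste(ind$fid, ind$iid)
  has_father <- paste(ind$fid, ind$pid) %in% key & ind$pid != "0"
  has_mother <- paste(ind$fid, ind$mid) %in% key & ind$mid != "0"
  founder <- ind$pid == "0" & ind$mid == "0"
  is_parent <- key %in% c(
    paste(ind$fid, ind$pid), paste(ind$fid, ind$mid)
  )
  is_case_child <- ind$pheno == "2" & has_father & has_mother
  is_control <- founder & ind$pheno == "1" & !is_parent
  n_unused_unaffected <- sum(ind$pheno == "1" & !founder & !is_parent)
  if (n_unused_unaffected > 0) {
    inform(paste0(
      n_unused_unaffected,
      " unaffected non-founder(s) contribute to neither trios nor controls."
    ))
  }

  child_idx <- which(is_case_child)
  father_idx <- match(paste(ind$fid, ind$pid)[child_idx], key)
  mother_idx <- match(paste(ind$fid, ind$mid)[child_idx], key)
  control_idx <- which(is_control)

  per_marker <- purrr::map(seq_len(n_mark), function(j) {
    a1 <- alleles[, 2 * j - 1]
    a2 <- alleles[, 2 * j]
    obs <- c(a1, a2)
    obs <- obs[obs != "0"]
    codes <- sort(unique(obs))
    if (length(codes) > 2) {
      abort(paste0("marker ", map$id[j], " has more than two alleles."))
    }
    if (length(codes) == 0) codes <- c("1", "2")
    counts <- table(factor(obs, levels = codes))
    minor <- codes[which.min(counts)] # ties: first in code order
    major <- if (length(codes) == 2) setdiff(codes, minor) else minor
    g <- (a1 == minor) + (a2 == minor)
    g[a1 == "0" | a2 == "0"] <- NA_integer_
    list(minor = minor, major = major, g = as.integer(g))
  })

  data <- purrr::map(per_marker, function(mk) {
    mixed_data(
      trios = tibble(
        father_g = mk$g[father_idx],
        mother_g = mk$g[mother_idx],
        child_g = mk$g[child_idx]
      ),
      controls = mk$g[control_idx]
    )
  })
  names(data) <- map$id

  markers <- map
  markers$allele_minor <- purrr::map_chr(per_marker, "minor")
  markers$allele_major <- purrr::map_chr(per_marker, "major")

  structure(
    list(markers = markers, data = data),
    class = "popfam_cohort"
  )
}

#' @export
print.popfam_cohort <- function(x, ...) {
  n <- x$data[[1]]
  cat("<popfam_cohort> ", nrow(x$markers), " marker(s), ",
    nrow(n$trios), " trios, ", nrow(n$controls), " controls\n",
    sep = ""
  )
  invisible(x)
}

#' Write a simulated mixed dataset as PED/MAP (+ JSON sidecar)
#'
#' Each trio becomes a three-person family (parents unphenotyped, affected
#' child) and each control a singleton unaffected founder. The minor allele
#' is written as code "1" and the major allele as code "2"; missing
#' genotypes as "0 0". When `model` and/or `seed` are given, a JSON sidecar
#' `<prefix>.json` records the simulation provenance.
#'
#' @param data A [mixed_data] object.
#' @param prefix Output path prefix; writes `<prefix>.ped`, `<prefix>.map`
#'   and optionally `<prefix>.json`.
#' @param marker_id Marker name for the MAP file.
#' @param model Optional [genetic_model] to record in the sidecar.
#' @param seed Optional seed to record in the sidecar.
#' @return The prefix, invisibly.
#' @export
write_ped <- function(data, prefix, marker_id = "SNP1", model = NULL,
                      seed = NULL) {
  stopifnot(inherits(data, "mixed_data"))
  pair <- function(g) {
    out <- character(length(g))
    out[is.na(g)] <- "0 0"
    out[!is.na(g) & g == 2] <- "1 1"
    out[!is.na(g) & g == 1] <- "1 2"
    out[!is.na(g) & g == 0] <- "2 2"
    out
  }
  tr <- data$trios
  lines <- character(0)
  if (nrow(tr) > 0) {
    fam <- paste0("T", seq_len(nrow(tr)))
    lines <- c(
      lines,
      paste(fam, "1", "0", "0", "1", "0", pair(tr$father_g)),
      paste(fam, "2", "0", "0", "2", "0", pair(tr$mother_g)),
      paste(fam, "3", "1", "2", "1", "2", pair(tr$child_g))
    )
  }
  if (nrow(data$controls) > 0) {
    fam <- paste0("C", seq_len(nrow(data$controls)))
    lines <- c(
      lines,
      paste(fam, "1", "0", "0", "1", "1", pair(data$controls$g))
    )
  }
  writeLines(lines, paste0(prefix, ".ped"))
  writeLines(paste("1", marker_id, "0", "1"), paste0(prefix, ".map"))
  if (!is.null(model) || !is.null(seed)) {
    side <- list(
      marker_id = marker_id,
      n_trios = nrow(tr), n_controls = nrow(data$controls),
      seed = seed
    )
    if (!is.null(model)) side$model <- unclass(model)
    jsonlite::write_json(side, paste0(prefix, ".json"),
      auto_unbox = TRUE, null = "null"
    )
  }
  invisible(prefix)
}
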