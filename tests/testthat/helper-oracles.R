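# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / enumeration and never call the code paths
# they are used to check.

# Transmission-phase brute force: enumerate every ordered allele pair
# compatible with each parent's genotype and every transmission choice;
# return NULL for a Mendelian-impossible triple, else the (unique) h and t.
oracle_transmissions <- function(fg, mg, cg) {
  pairs <- function(g) switch(as.character(g),
    "0" = list(c(0L, 0L)),
    "1" = list(c(0L, 1L), c(1L, 0L)),
    "2" = list(c(1L, 1L))
  )
  h <- (fg == 1L) + (mg == 1L)
  ts <- integer(0)
  for (fp in pairs(fg)) {
    for (mp in pairs(mg)) {
      for (i in 1:2) {
        for (j in 1:2) {
          if (fp[i] + mp[j] == cg) {
            ts <- c(ts, (fg == 1L) * fp[i] + (mg == 1L) * mp[j])
          }
        }
      }
    }
  }
  if (length(ts) == 0) {
    return(NULL)
  }
  stopifnot(length(unique(ts)) == 1) # t is determined by the genotypes
  list(h = as.integer(h), t = ts[[1]])
}

# Classical two-sample z-test of allele proportions with pooled variance,
# on 2N case and 2M control alleles.
oracle_prop_z <- function(case_g, control_g) {
  n1 <- 2 * length(case_g)
  n2 <- 2 * length(control_g)
  p1 <- sum(case_g) / n1
  p2 <- sum(control_g) / n2
  pp <- (sum(case_g) + sum(control_g)) / (n1 + n2)
  (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
}

# Exact conditional distribution of accepted-trio marker genotype triples
# (father_g, mother_g, child_g), by enumerating the ordered
# parental-haplotype space and both transmission choices. Returns a named
# vector of probabilities keyed "fg:mg:cg".
oracle_trio_dist <- function(model) {
  q <- c(
    model$marker_maf * model$daf,
    model$marker_maf * (1 - model$daf),
    (1 - model$marker_maf) * model$daf,
    (1 - model$marker_maf) * (1 - model$daf)
  )
  dmax <- min(
    model$marker_maf * (1 - model$daf),
    (1 - model$marker_maf) * model$daf
  )
  d <- model$dprime * dmax
  q <- q + c(d, -d, -d, d)
  hm <- c(1L, 1L, 0L, 0L)
  hd <- c(1L, 0L, 1L, 0L)
  pen <- c(model$f0, model$f1, model$f2)
  out <- numeric(0)
  for (h1 in 1:4) for (h2 in 1:4) for (h3 in 1:4) for (h4 in 1:4) {
    w <- q[h1] * q[h2] * q[h3] * q[h4]
    for (tf in c(h1, h2)) for (tm in c(h3, h4)) {
      key <- paste(hm[h1] + hm[h2], hm[h3] + hm[h4], hm[tf] + hm[tm],
        sep = ":"
      )
      p <- w * 0.25 * pen[hd[tf] + hd[tm] + 1L]
      out[key] <- (out[key] %||% 0) + p
    }
  }
  out / sum(out)
}

# Exact marker genotype distribution of an unaffected-conditional control.
oracle_control_dist <- function(model) {
  q <- c(
    model$marker_maf * model$daf,
    model$marker_maf * (1 - model$daf),
    (1 - model$marker_maf) * model$daf,
    (1 - model$marker_maf) * (1 - model$daf)
  )
  dmax <- min(
    model$marker_maf * (1 - model$daf),
    (1 - model$marker_maf) * model$daf
  )
  d <- model$dprime * dmax
  q <- q + c(d, -d, -d, d)
  hm <- c(1L, 1L, 0L, 0L)
  hd <- c(1L, 0L, 1L, 0L)
  pen <- c(model$f0, model$f1, model$f2)
  out <- numeric(3)
  for (h1 in 1:4) for (h2 in 1:4) {
    g <- hm[h1] + hm[h2]
    out[g + 1L] <- out[g + 1L] +
      q[h1] * q[h2] * (1 - pen[hd[h1] + hd[h2] + 1L])
  }
  out / sum(out)
}

`%||%` <- function(x, y) if (is.null(x) || is.na(x)) y else x
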