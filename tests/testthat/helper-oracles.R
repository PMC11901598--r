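# Brute-force oracles, written as plain loops over individual calls and
# deliberately independent of the package's dplyr pipelines.

# list keyed "locus pos allele" -> sorted character vector of lineages
# in which that allele state is observed
oracle_presence <- function(geno, pm) {
  pres <- list()
  lin_of <- setNames(pm$lineage, pm$sample)
  for (r in seq_len(nrow(geno))) {
    lin <- lin_of[[geno$sample[r]]]
    for (a in c(geno$a1[r], geno$a2[r])) {
      if (is.na(a)) next
      key <- paste(geno$locus[r], geno$pos[r], a)
      pres[[key]] <- union(pres[[key]], lin)
    }
  }
  lapply(pres, sort)
}

oracle_private <- function(geno, pm) {
  pres <- oracle_presence(geno, pm)
  out <- setNames(rep(0L, length(unique(pm$lineage))), unique(pm$lineage))
  for (lins in pres) {
    if (length(lins) == 1) out[lins] <- out[lins] + 1L
  }
  out
}

oracle_shared <- function(geno, pm, focal) {
  pres <- oracle_presence(geno, pm)
  others <- setdiff(unique(pm$lineage), focal)
  out <- setNames(rep(0L, length(others)), others)
  for (lins in pres) {
    if (!focal %in% lins) next
    for (l in intersect(lins, others)) out[l] <- out[l] + 1L
  }
  out
}

oracle_exclusive <- function(geno, pm, focal) {
  pres <- oracle_presence(geno, pm)
  others <- setdiff(unique(pm$lineage), focal)
  out <- setNames(rep(0L, length(others)), others)
  for (lins in pres) {
    if (length(lins) == 2 && focal %in% lins) {
      l <- setdiff(lins, focal)
      out[l] <- out[l] + 1L
    }
  }
  out
}

# clade sharing for one member set: c(shared, exclusive)
oracle_clade <- function(geno, pm, focal, members) {
  pres <- oracle_presence(geno, pm)
  shared <- 0L
  exclusive <- 0L
  for (lins in pres) {
    if (!focal %in% lins) next
    if (!any(members %in% lins)) next
    shared <- shared + 1L
    outside <- setdiff(lins, c(focal, members))
    if (length(outside) == 0) exclusive <- exclusive + 1L
  }
  c(shared = shared, exclusive = exclusive)
}

oracle_focal_totals <- function(geno, pm, focal) {
  pres <- oracle_presence(geno, pm)
  total <- 0L
  private <- 0L
  for (lins in pres) {
    if (!focal %in% lins) next
    total <- total + 1L
    if (length(lins) == 1) private <- private + 1L
  }
  c(total = total, private = private)
}

# pairwise SH by an explicit per-variant loop over two samples
oracle_sh <- function(geno, sa, sb, denominator = "either") {
  ga <- geno[geno$sample == sa, ]
  gb <- geno[geno$sample == sb, ]
  key <- paste(ga$locus, ga$pos)
  gb <- gb[match(key, paste(gb$locus, gb$pos)), ]
  h <- 0L
  m <- 0L
  for (i in seq_len(nrow(ga))) {
    if (is.na(ga$a1[i]) || is.na(gb$a1[i])) next
    het_a <- ga$a1[i] != ga$a2[i]
    het_b <- gb$a1[i] != gb$a2[i]
    comparable <- if (denominator == "either") het_a || het_b else
      het_a && het_b
    if (!comparable) next
    h <- h + 1L
    if (het_a && het_b && ga$a1[i] == gb$a1[i] && ga$a2[i] == gb$a2[i]) {
      m <- m + 1L
    }
  }
  if (h == 0) NA_real_ else m / h
}
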