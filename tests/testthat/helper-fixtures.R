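# Shared fixtures, built in code.
#
# F1: 4 SNPs x 4 samples; lineages X (focal: x1, x2), B (b1), C (c1),
# clade K1 = {B, C}.  Its sharing structure is known by hand enumeration:
# 8 (variant, allele) states observed; X carries 7 of them (all but v3:0),
# one private to X (v4:1, a single copy in x1); B and C each share 5 states
# with X; v2:1 is exclusive to {X, B}, v1:1 exclusive to {X, C}; clade K1
# shares 6 / 6 exclusively.  With focal_min_carriers = 1 the ubiquity rule
# drops v3 (its alt is carried in X, B and C), keeping {v1, v2, v4}.

f1_calls <- function() {
  # per variant: list(ref, alt, calls for x1, x2, b1, c1 as "a/b" strings)
  list(
    v1 = list(ref = "A", alt = "G", gt = c("0/1", "0/0", "0/0", "0/1")),
    v2 = list(ref = "C", alt = "T", gt = c("0/0", "0/1", "0/1", "0/0")),
    v3 = list(ref = "G", alt = "A", gt = c("1/1", "1/1", "0/1", "0/1")),
    v4 = list(ref = "T", alt = "C", gt = c("0/1", "0/0", "0/0", "0/0"))
  )
}

f1_geno <- function() {
  spec <- f1_calls()
  samples <- c("x1", "x2", "b1", "c1")
  dp <- matrix(c(
    15L, 22L, 31L, 44L,
    12L, 18L, 25L, 30L,
    40L, 35L, 28L, 21L,
    11L, 13L, 17L, 19L
  ), nrow = 4, byrow = TRUE)
  rows <- lapply(seq_along(spec), function(i) {
    v <- spec[[i]]
    a <- do.call(rbind, strsplit(v$gt, "/"))
    tibble::tibble(
      locus = names(spec)[i], pos = i * 6L - 1L, ref = v$ref, alt = v$alt,
      sample = samples,
      a1 = as.integer(a[, 1]), a2 = as.integer(a[, 2]),
      dp = dp[i, ], site_dp = NA_real_
    )
  })
  polyshare::geno_tbl(dplyr::bind_rows(rows))
}

f1_popmap <- function() {
  polyshare::popmap(
    tibble::tibble(
      sample = c("x1", "x2", "b1", "c1"),
      lineage = c("X", "X", "B", "C"),
      clade = c(NA, NA, "K1", "K1")
    ),
    focal = "X"
  )
}

# random genotype table over `samples`; a fraction of variants triallelic,
# calls missing with probability p_miss
rand_geno <- function(n_var, samples, seed, p_miss = 0.2, p_tri = 0.15,
                      with_depth = TRUE) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    rows <- lapply(seq_len(n_var), function(i) {
      tri <- stats::runif(1) < p_tri
      ref <- sample(bases, 1)
      alt <- sample(setdiff(bases, ref), if (tri) 2 else 1)
      n_all <- 1L + length(alt)
      k <- length(samples)
      a1 <- sample.int(n_all, k, replace = TRUE) - 1L
      a2 <- sample.int(n_all, k, replace = TRUE) - 1L
      miss <- stats::runif(k) < p_miss
      a1[miss] <- NA_integer_
      a2[miss] <- NA_integer_
      tibble::tibble(
        locus = sprintf("L%03d", i), pos = sample.int(200L, 1),
        ref = ref, alt = paste(alt, collapse = ","), sample = samples,
        a1 = a1, a2 = a2,
        dp = if (with_depth) sample(5:80, k, replace = TRUE) else NA_integer_,
        site_dp = NA_real_
      )
    })
    polyshare::geno_tbl(dplyr::bind_rows(rows))
  })
}

# random popmap: samples split round-robin over lineages, lineages into clades
rand_popmap <- function(samples, n_lineages = 4, seed = 1) {
  withr::with_seed(seed, {
    lineages <- paste0("P", seq_len(n_lineages))
    assign <- rep(lineages, length.out = length(samples))
    clade <- setNames(
      rep(c("K1", "K2"), length.out = n_lineages), lineages
    )
    clade[1] <- NA  # focal lineage sits outside the clades
    polyshare::popmap(
      tibble::tibble(sample = samples, lineage = assign,
                     clade = unname(clade[assign])),
      focal = lineages[1]
    )
  })
}

# compare genotype tables by content, ignoring bookkeeping attributes
geno_df <- function(g) {
  df <- as.data.frame(g)
  attributes(df) <- attributes(df)[c("names", "class", "row.names")]
  rownames(df) <- NULL
  df
}
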