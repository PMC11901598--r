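#' Tidy genotype tables
#'
#' The central data structure of polyshare is a plain long tibble holding one
#' row per (variant, sample) pair -- the tidy equivalent of a samples-by-SNPs
#' genotype matrix.  Columns:
#'
#' * `locus`, `pos` -- variant identity (GBS locus id and 1-based position
#'   within it; together the unique key).
#' * `ref`, `alt` -- reference allele string and comma-separated alternate
#'   allele strings (`""` when the site is monomorphic in the VCF).
#'   Allele index 0 is `ref`, index k >= 1 the k-th alternate.
#' * `sample` -- sample identifier.
#' * `a1`, `a2` -- the unordered diploid call, stored canonically with
#'   `a1 <= a2`; both `NA` for a missing genotype.  Phase is never retained:
#'   every statistic downstream is phase-free.
#' * `dp` -- per-genotype read depth (`NA` = unknown).
#' * `site_dp` -- site-level depth from the VCF INFO field (`NA` = unknown),
#'   repeated across the variant's rows.
#'
#' `geno_tbl()` validates a data frame against this contract, canonicalises
#' `a1`/`a2`, and returns a tibble.  Every row set must be a complete
#' variants-by-samples grid.
#'
#' @param x A data frame with the columns described above (`dp` and `site_dp`
#'   may be omitted and default to unknown).
#' @return A validated tibble, ordered variant-major.
#' @examples
#' geno_tbl(tibble::tibble(
#'   locus = "loc1", pos = 7L, ref = "A", alt = "G",
#'   sample = c("s1", "s2"), a1 = c(0L, NA), a2 = c(1L, NA)
#' ))
#' @export
geno_tbl <- function(x) {
  need <- c("locus", "pos", "ref", "alt", "sample", "a1", "a2")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    ps_input_error(paste0(
      "genotype table lacks column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  x <- as_tibble(x)
  if (!"dp" %in% names(x)) x$dp <- NA_integer_
  if (!"site_dp" %in% names(x)) x$site_dp <- NA_real_
  x <- mutate(
    x,
    locus = as.character(.data$locus),
    pos = as.integer(.data$pos),
    ref = as.character(.data$ref),
    alt = ifelse(is.na(.data$alt), "", as.character(.data$alt)),
    sample = as.character(.data$sample),
    a1 = as.integer(.data$a1),
    a2 = as.integer(.data$a2),
    dp = as.integer(.data$dp),
    site_dp = as.numeric(.data$site_dp)
  )
  lo <- pmin(x$a1, x$a2)
  hi <- pmax(x$a1, x$a2)
  half <- is.na(x$a1) != is.na(x$a2)
  if (any(half)) {
    warn(sprintf("%d half-call(s) converted to MISSING", sum(half)))
    lo[half] <- NA_integer_
    hi[half] <- NA_integer_
  }
  x$a1 <- lo
  x$a2 <- hi
  if (any(x$pos < 1L, na.rm = TRUE)) ps_input_error("positions must be >= 1")
  vt <- variant_tbl(x)
  n_alleles <- 1L + lengths(split_alt(vt$alt))
  key <- paste(x$locus, x$pos)
  n_all <- n_alleles[match(key, paste(vt$locus, vt$pos))]
  bad <- (!is.na(x$a1) & x$a1 >= n_all) | (!is.na(x$a2) & x$a2 >= n_all)
  if (any(bad)) {
    ps_input_error("allele index out of range for its variant's allele list")
  }
  if (any(vt$ref == "")) ps_input_error("ref allele must be non-empty")
  alt_split <- split_alt(vt$alt)
  if (any(map2_lgl(vt$ref, alt_split, function(r, a) any(a == r)))) {
    ps_input_error("ref allele duplicated among alt alleles")
  }
  samples <- unique(x$sample)
  if (nrow(x) != nrow(vt) * length(samples) ||
      anyDuplicated(paste(key, x$sample))) {
    ps_input_error("genotype table must be a complete variants x samples grid")
  }
  x <- arrange(x, match(paste(.data$locus, .data$pos), paste(vt$locus, vt$pos)),
               match(.data$sample, samples))
  attr(x, "samples") <- samples
  x
}

#' Per-variant metadata of a genotype table
#'
#' @param geno A genotype tibble (see [geno_tbl()]).
#' @return One row per variant: `locus`, `pos`, `ref`, `alt`, `site_dp`,
#'   in first-appearance order.
#' @export
variant_tbl <- function(geno) {
  distinct(as_tibble(geno), .data$locus, .data$pos, .data$ref, .data$alt,
           .data$site_dp)
}

#' Sample identifiers of a genotype table
#'
#' An empty table (zero variants) retains its sample panel through the
#' `"samples"` attribute set by [geno_tbl()] and [read_vcf()].
#'
#' @param geno A genotype tibble.
#' @return Character vector of sample ids.
#' @export
geno_samples <- function(geno) {
  if (nrow(geno) == 0) {
    return(attr(geno, "samples") %||% character(0))
  }
  unique(geno$sample)
}

#' @describeIn variant_tbl Number of distinct variants in the table.
#' @export
n_variants <- function(geno) nrow(distinct(as_tibble(geno), .data$locus, .data$pos))

# matrix view used by pairwise statistics: variants x samples integer matrices
geno_matrices <- function(geno) {
  vt <- variant_tbl(geno)
  samples <- geno_samples(geno)
  vkey <- paste(vt$locus, vt$pos)
  i <- match(paste(geno$locus, geno$pos), vkey)
  j <- match(geno$sample, samples)
  shape <- function(col) {
    m <- matrix(NA_integer_, nrow = nrow(vt), ncol = length(samples),
                dimnames = list(vkey, samples))
    m[cbind(i, j)] <- col
    m
  }
  list(a1 = shape(geno$a1), a2 = shape(geno$a2), dp = shape(geno$dp),
       variants = vt, samples = samples)
}

# keep only the given variants (semi-join on the key), preserving order
keep_variants <- function(geno, keys_keep) {
  out <- geno[paste(geno$locus, geno$pos) %in% keys_keep, , drop = FALSE]
  attr(out, "samples") <- geno_samples(geno)
  out
}

#' @describeIn variant_tbl Character keys `"locus pos"` of the table's
#'   variants, in order.
#' @export
variant_keys <- function(geno) unique(paste(geno$locus, geno$pos))
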