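#' Read a VCF file into a genotype tibble
#'
#' Parses a VCF v4.x file (GT required, DP optional at the genotype and/or
#' site level) into the long tidy genotype format of [geno_tbl()].  Phased and
#' unphased genotypes are treated identically (calls are unordered); half-calls
#' and non-diploid genotypes are converted to MISSING with a warning.
#' Multiallelic records are kept as single variants -- each alternate allele is
#' a distinct countable allele state.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A genotype tibble; the CHROM column becomes `locus`.
#' @seealso [write_vcf()] for the inverse, a lossless round trip on this data
#'   model.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) ps_input_error(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^##fileformat=VCF", lines[1])) {
    ps_input_error(paste0(path, ": line 1: missing ##fileformat=VCF header"))
  }
  hdr_i <- which(grepl("^#CHROM\t", lines))[1]
  if (is.na(hdr_i)) ps_input_error(paste0(path, ": no #CHROM header line"))
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10 || hdr[9] != "FORMAT") {
    ps_input_error(paste0(path, ": line ", hdr_i,
                          ": header lacks FORMAT/sample columns"))
  }
  samples <- hdr[-(1:9)]
  if (anyDuplicated(samples)) {
    ps_input_error(paste0(path, ": duplicate sample id: ",
                          samples[duplicated(samples)][1]))
  }
  body_i <- seq.int(hdr_i + 1L, length.out = max(0L, length(lines) - hdr_i))
  body_i <- body_i[nzchar(lines[body_i])]
  nfield <- lengths(strsplit(lines[body_i], "\t", fixed = TRUE))
  bad <- body_i[nfield != length(hdr)]
  if (length(bad)) {
    ps_input_error(paste0(path, ": line ", bad[1], ": expected ",
                          length(hdr), " fields, found ",
                          nfield[match(bad[1], body_i)]))
  }

  if (length(body_i) == 0) {
    out <- geno_tbl(tibble(
      locus = character(0), pos = integer(0), ref = character(0),
      alt = character(0), sample = character(0),
      a1 = integer(0), a2 = integer(0), dp = integer(0), site_dp = numeric(0)
    ))
    attr(out, "samples") <- samples
    return(out)
  }

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n_var <- nrow(fix)
  alt <- fix[, "ALT"]
  alt[is.na(alt) | alt == "."] <- ""
  fmt <- vcf@gt[, "FORMAT"]
  gt <- vcfR::extract.gt(vcf, element = "GT", convertNA = FALSE,
                         IDtoRowNames = FALSE)
  has_dp <- any(grepl("(^|:)DP(:|$)", fmt))
  dp <- if (has_dp) {
    suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE,
                                      IDtoRowNames = FALSE))
  } else {
    matrix(NA_real_, n_var, length(samples))
  }
  site_dp <- suppressWarnings(as.numeric(
    sub("^.*?DP=([0-9.]+).*$", "\\1",
        ifelse(grepl("(^|;)DP=", fix[, "INFO"]), fix[, "INFO"], NA))
  ))

  calls <- parse_gt(as.vector(t(gt)))
  out <- tibble(
    locus = rep(fix[, "CHROM"], each = length(samples)),
    pos = rep(as.integer(fix[, "POS"]), each = length(samples)),
    ref = rep(fix[, "REF"], each = length(samples)),
    alt = rep(alt, each = length(samples)),
    sample = rep(samples, times = n_var),
    a1 = calls$a1,
    a2 = calls$a2,
    dp = as.integer(as.vector(t(dp))),
    site_dp = rep(site_dp, each = length(samples))
  )
  geno_tbl(out)
}

#' Write a genotype tibble to a VCF v4.2 file
#'
#' Genotypes are serialised unphased in canonical order (`a/b` with a <= b,
#' `./.` for missing), per-genotype DP is emitted whenever any call depth is
#' known, and site depth goes to `INFO/DP`.  `read_vcf(write_vcf(x))` is the
#' identity on the data model (allele sets, missingness, depths).
#'
#' @param geno A genotype tibble.
#' @param path Output file path.
#' @param samples Sample panel to write; defaults to the table's samples
#'   (needed explicitly only for a zero-variant table with no `"samples"`
#'   attribute).
#' @param provenance Optional character vector written as extra `##` meta
#'   lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path, samples = NULL, provenance = NULL) {
  samples <- samples %||% geno_samples(geno)
  vt <- variant_tbl(geno)
  has_dp <- nrow(geno) > 0 && any(!is.na(geno$dp))
  meta <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=polyshare_v", as.character(packageVersion("polyshare"))),
    if (!is.null(provenance)) paste0("##polyshare_", provenance),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth at the site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  if (nrow(vt) == 0) {
    write_lines_plain(meta, path)
    return(invisible(path))
  }
  gm <- geno_matrices(geno)
  gt_chr <- matrix(format_gt(gm$a1, gm$a2), nrow = nrow(vt))
  if (has_dp) {
    dp_chr <- matrix(ifelse(is.na(gm$dp), ".", as.character(gm$dp)),
                     nrow = nrow(vt))
    cell <- matrix(paste0(gt_chr, ":", dp_chr), nrow = nrow(vt))
    fmt <- "GT:DP"
  } else {
    cell <- gt_chr
    fmt <- "GT"
  }
  info <- ifelse(is.na(vt$site_dp), ".", paste0("DP=", vt$site_dp))
  recs <- paste(
    vt$locus, vt$pos, ".", vt$ref, ifelse(vt$alt == "", ".", vt$alt),
    ".", ".", info, fmt,
    apply(cell, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  write_lines_plain(c(meta, recs), path)
  invisible(path)
}
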