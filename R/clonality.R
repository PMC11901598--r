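#' Shared heterozygosity of a pair of call series
#'
#' The SH index is the proportion of shared identically heterozygous SNPs of
#' a pair of samples: among the sites where both calls are known and at
#' least one of the two is heterozygous (the comparable sites), the fraction
#' at which both are heterozygous *and* identical as unordered allele pairs
#' (so `0/1 == 1/0` but `0/1 != 0/2`).  With no comparable site the index is
#' undefined (`NA`).  Pairs of ramets of one clone approach SH = 1;
#' sexually produced pairs fall well below the conventional 0.9 threshold.
#'
#' @param a,b Call series over the same variants, either as character
#'   genotype vectors (`"0/1"`, `"1|0"`, `"./."`) or as two-column
#'   matrices/data frames of allele indices.
#' @param denominator `"either"` (default): sites heterozygous in at least
#'   one of the pair; `"both"`: sites heterozygous in both, offered for
#'   sensitivity analysis.
#' @return The SH value in `[0, 1]`, or `NA` when undefined; the number of
#'   comparable sites is attached as attribute `"n_comparable"`.
#' @examples
#' shared_heterozygosity(c("0/1", "0/1", "0/1", "0/0"),
#'                       c("0/1", "0/1", "1/1", "0/0"))  # 2/3
#' @export
shared_heterozygosity <- function(a, b, denominator = c("either", "both")) {
  denominator <- match.arg(denominator)
  a <- as_call_pair(a)
  b <- as_call_pair(b)
  if (length(a$a1) != length(b$a1)) {
    ps_input_error("call series must have equal length over the same variants")
  }
  sh_core(a$a1, a$a2, b$a1, b$a2, denominator)
}

as_call_pair <- function(x) {
  if (is.character(x)) {
    suppressWarnings(parse_gt(x))
  } else if (is.matrix(x) && ncol(x) == 2) {
    a1 <- as.integer(x[, 1])
    a2 <- as.integer(x[, 2])
    list(a1 = pmin(a1, a2), a2 = pmax(a1, a2))
  } else if (is.data.frame(x) && ncol(x) == 2) {
    a1 <- as.integer(x[[1]])
    a2 <- as.integer(x[[2]])
    list(a1 = pmin(a1, a2), a2 = pmax(a1, a2))
  } else if (is.list(x) && all(c("a1", "a2") %in% names(x))) {
    list(a1 = pmin(x$a1, x$a2), a2 = pmax(x$a1, x$a2))
  } else {
    ps_input_error("calls must be GT strings or a two-column allele structure")
  }
}

sh_core <- function(a1, a2, b1, b2, denominator = "either") {
  known <- !is.na(a1) & !is.na(b1)
  het_a <- known & a1 != a2
  het_b <- known & b1 != b2
  comparable <- if (denominator == "either") het_a | het_b else het_a & het_b
  n <- sum(comparable)
  if (n == 0L) {
    return(structure(NA_real_, n_comparable = 0L))
  }
  m <- sum(comparable & het_a & het_b & a1 == b1 & a2 == b2)
  structure(m / n, n_comparable = n)
}

#' Pairwise shared heterozygosity across a genotype table
#'
#' Scores every unordered sample pair -- by default only pairs within a
#' lineage, as clonal reproduction is an intra-lineage question -- and flags
#' clonemate pairs (SH strictly above the threshold).
#'
#' @param geno A genotype tibble.
#' @param pm A popmap covering the samples.
#' @param scope `"within_lineage"` (default) or `"all_pairs"`.
#' @param threshold Clone threshold on SH (strict `>`).  Default 0.9.
#' @param denominator See [shared_heterozygosity()].
#' @return A `sh_result` tibble: `sample_a`, `sample_b`, `lineage` (`NA` for
#'   cross-lineage pairs), `n_sites`, `sh`, `is_clone`.  Lineages with fewer
#'   than two samples simply contribute no pairs.
#' @export
pairwise_sh <- function(geno, pm, scope = c("within_lineage", "all_pairs"),
                        threshold = 0.9,
                        denominator = c("either", "both")) {
  scope <- match.arg(scope)
  denominator <- match.arg(denominator)
  check_threshold(threshold)
  samples <- geno_samples(geno)
  lin <- pm$lineage[match(samples, pm$sample)]
  if (any(is.na(lin))) {
    ps_input_error("popmap does not cover all samples in the genotype table")
  }
  gm <- geno_matrices(geno)
  pairs <- if (scope == "within_lineage") {
    by_lin <- split(seq_along(samples), lin)
    pair_mats <- map(by_lin[lengths(by_lin) >= 2], function(i) combn(i, 2))
    if (length(pair_mats)) do.call(cbind, pair_mats) else
      matrix(integer(0), nrow = 2)
  } else if (length(samples) >= 2) {
    combn(seq_along(samples), 2)
  } else {
    matrix(integer(0), nrow = 2)
  }
  n_pairs <- ncol(pairs)
  sh <- numeric(n_pairs)
  n_sites <- integer(n_pairs)
  for (k in seq_len(n_pairs)) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    val <- sh_core(gm$a1[, i], gm$a2[, i], gm$a1[, j], gm$a2[, j], denominator)
    sh[k] <- as.numeric(val)
    n_sites[k] <- attr(val, "n_comparable")
  }
  i <- pairs[1, ]
  j <- pairs[2, ]
  out <- tibble(
    sample_a = samples[i],
    sample_b = samples[j],
    lineage = ifelse(lin[i] == lin[j], lin[i], NA_character_),
    n_sites = n_sites,
    sh = sh,
    is_clone = !is.na(sh) & sh > threshold
  )
  structure(out, threshold = threshold, denominator = denominator,
            class = c("sh_result", class(tibble())))
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    ps_input_error("threshold must be a single value in [0, 1]")
  }
  invisible(threshold)
}

#' Classify clonemate pairs
#'
#' Applies the strict rule SH > threshold ("above 0.9"); pairs with
#' undefined SH are never flagged.
#'
#' @param shres A [pairwise_sh()] result.
#' @param threshold Clone threshold in `[0, 1]`; defaults to the one stored
#'   in `shres`.
#' @return The clonemate pairs (possibly zero rows), with `is_clone`
#'   recomputed at `threshold`.
#' @export
classify_clones <- function(shres, threshold = attr(shres, "threshold") %||% 0.9) {
  check_threshold(threshold)
  out <- as_tibble(shres)
  out$is_clone <- !is.na(out$sh) & out$sh > threshold
  out[out$is_clone, , drop = FALSE]
}

#' @export
tidy.sh_result <- function(x, ...) as_tibble(x)

#' @export
glance.sh_result <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_defined = sum(!is.na(x$sh)),
    n_clone_pairs = sum(x$is_clone),
    threshold = attr(x, "threshold"),
    median_sh = median(x$sh, na.rm = TRUE),
    max_sh = if (all(is.na(x$sh))) NA_real_ else max(x$sh, na.rm = TRUE)
  )
}

#' Threshold point plot of pairwise shared heterozygosity
#'
#' One point per intra-lineage sample pair, coloured by lineage, with a
#' horizontal line at the clone threshold.
#'
#' @param object A [pairwise_sh()] result.
#' @param threshold Threshold line position; defaults to the stored one.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sh_result <- function(object, threshold = attr(object, "threshold"),
                               ...) {
  rows <- as_tibble(object)
  rows <- rows[!is.na(rows$lineage) & !is.na(rows$sh), , drop = FALSE]
  if (nrow(rows) == 0) {
    warn("no defined intra-lineage SH values to plot")
  }
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$lineage, y = .data$sh,
                                     colour = .data$lineage)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, size = 1.8, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, colour = "deeppink") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "shared heterozygosity (SH)",
                  colour = "lineage") +
    ggplot2::theme_minimal()
}

#' Serialise an SH result
#'
#' @param shres A [pairwise_sh()] result.
#' @param path Output TSV path.
#' @param provenance Optional extra `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_sh_result <- function(shres, path, provenance = NULL) {
  hdr <- c(
    if (!is.null(provenance)) paste0("# ", provenance),
    sprintf("# threshold=%s denominator=%s", attr(shres, "threshold"),
            attr(shres, "denominator"))
  )
  body <- utils::capture.output(
    utils::write.table(as.data.frame(shres), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  )
  write_lines_plain(c(hdr, body), path)
  invisible(path)
}
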