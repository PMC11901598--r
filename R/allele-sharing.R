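#' Build the per-lineage allele-count table
#'
#' Converts a genotype table into the genpop-style long count table on which
#' all sharing statistics operate: one row per (variant, allele state,
#' lineage) with at least one observed allele copy, with the copy count.
#' Missing calls contribute nothing.  An allele means a (site, allele-state)
#' pair; the reference allele is an allele like any other.
#'
#' @param geno A genotype tibble.
#' @param pm A popmap covering the table's samples.
#' @param exclude Optional character vector of lineages to drop before
#'   counting (e.g. hybrid lineages other than the focal, so that sharing is
#'   assessed against diploid species only).
#' @return A tibble with columns `locus`, `pos`, `allele`, `lineage`,
#'   `n_copies`, carrying attributes `lineages` (all retained lineage
#'   labels), `focal`, and `clades`.  Class `allele_counts`.
#' @export
build_allele_counts <- function(geno, pm, exclude = NULL) {
  focal <- focal_lineage(pm)
  if (focal %in% exclude) ps_input_error("cannot exclude the focal lineage")
  pm_used <- pm[!pm$lineage %in% exclude, , drop = FALSE]
  g <- as_tibble(geno)[, c("locus", "pos", "sample", "a1", "a2")]
  g <- g[g$sample %in% pm_used$sample, , drop = FALSE]
  if (nrow(g) > 0 && !all(geno_samples(geno) %in% pm$sample)) {
    ps_input_error("popmap does not cover all samples in the genotype table")
  }
  g$lineage <- pm_used$lineage[match(g$sample, pm_used$sample)]
  copies <- tibble(
    locus = c(g$locus, g$locus), pos = c(g$pos, g$pos),
    allele = c(g$a1, g$a2), lineage = c(g$lineage, g$lineage)
  )
  copies <- copies[!is.na(copies$allele), , drop = FALSE]
  out <- count(copies, .data$locus, .data$pos, .data$allele, .data$lineage,
               name = "n_copies")
  out <- arrange(out, .data$locus, .data$pos, .data$allele, .data$lineage)
  attr(out, "lineages") <- unique(pm_used$lineage)
  attr(out, "focal") <- focal
  attr(out, "clades") <- lineage_clades(pm_used)
  class(out) <- c("allele_counts", class(out))
  out
}

counts_lineages <- function(counts) {
  attr(counts, "lineages") %||% unique(counts$lineage)
}

counts_focal <- function(counts) {
  attr(counts, "focal") %||%
    ps_input_error("allele-count table has no focal lineage attribute")
}

# presence of each (variant, allele) per lineage plus how many lineages carry it
presence_by_allele <- function(counts) {
  pres <- distinct(as_tibble(counts), .data$locus, .data$pos, .data$allele,
                   .data$lineage)
  pres$key <- paste(pres$locus, pres$pos, pres$allele)
  n_lin <- count(pres, .data$key, name = "n_lineages")
  pres$n_lineages <- n_lin$n_lineages[match(pres$key, n_lin$key)]
  pres
}

complete_lineages <- function(df, lineages, col) {
  out <- tibble(lineage = lineages)
  out[[col]] <- df[[col]][match(lineages, df$lineage)]
  out[[col]][is.na(out[[col]])] <- 0L
  out
}

#' Private alleles per lineage
#'
#' A private allele is observed in exactly one lineage of the dataset.
#'
#' @param counts An [build_allele_counts()] table.
#' @return A tibble `lineage`, `n_private` covering every lineage (zeros
#'   included).
#' @export
private_alleles <- function(counts) {
  pres <- presence_by_allele(counts)
  priv <- count(pres[pres$n_lineages == 1L, ], .data$lineage,
                name = "n_private")
  complete_lineages(priv, counts_lineages(counts), "n_private")
}

#' Alleles shared between the focal lineage and each other lineage
#'
#' @param counts An [build_allele_counts()] table.
#' @return A tibble `lineage`, `n_shared`: for each non-focal lineage, the
#'   number of (site, allele) states present in both it and the focal
#'   lineage.
#' @export
shared_alleles <- function(counts) {
  focal <- counts_focal(counts)
  pres <- presence_by_allele(counts)
  focal_keys <- pres$key[pres$lineage == focal]
  other <- pres[pres$lineage != focal & pres$key %in% focal_keys, ]
  sh <- count(other, .data$lineage, name = "n_shared")
  complete_lineages(sh, setdiff(counts_lineages(counts), focal), "n_shared")
}

#' Alleles exclusively shared with each other lineage
#'
#' An exclusively shared allele is present in exactly two lineages: the
#' focal one and the lineage reported.
#'
#' @param counts An [build_allele_counts()] table.
#' @return A tibble `lineage`, `n_exclusive` over all non-focal lineages.
#' @export
exclusively_shared <- function(counts) {
  focal <- counts_focal(counts)
  pres <- presence_by_allele(counts)
  focal_keys <- pres$key[pres$lineage == focal]
  other <- pres[pres$lineage != focal & pres$n_lineages == 2L &
                  pres$key %in% focal_keys, ]
  ex <- count(other, .data$lineage, name = "n_exclusive")
  complete_lineages(ex, setdiff(counts_lineages(counts), focal), "n_exclusive")
}

# totals for the focal lineage: alleles observed, private, and the
# percentage denominator (total - private, the "non-private" alleles)
focal_totals <- function(counts) {
  focal <- counts_focal(counts)
  pres <- presence_by_allele(counts)
  fp <- pres[pres$lineage == focal, ]
  total <- nrow(fp)
  private <- sum(fp$n_lineages == 1L)
  list(total = total, private = private, denominator = total - private)
}

#' Clade-aggregated allele sharing
#'
#' A clade shares an allele with the focal lineage when at least one member
#' lineage carries it; the allele is exclusively shared with the clade when
#' no non-focal lineage outside the clade carries it.  Unions of clades are
#' treated as merged clades.
#'
#' @param counts An [build_allele_counts()] table.
#' @param clades Named list clade -> member lineages; defaults to the clades
#'   recorded in the popmap the table was built from.
#' @param unions Optional list of character vectors of clade names to merge
#'   (each reported as `"a+b"`).
#' @return A tibble `group`, `n_shared`, `n_exclusive`.
#' @export
clade_sharing <- function(counts, clades = NULL, unions = NULL) {
  focal <- counts_focal(counts)
  clades <- clades %||% attr(counts, "clades")
  if (is.null(clades) || length(clades) == 0) {
    ps_input_error("no clade definitions available")
  }
  if (any(map_lgl(clades, function(m) focal %in% m))) {
    ps_input_error("a clade may not contain the focal lineage")
  }
  groups <- clades
  for (u in unions) {
    missing_cl <- setdiff(u, names(clades))
    if (length(missing_cl)) {
      ps_input_error(paste0("unknown clade in union: ",
                            paste(missing_cl, collapse = ", ")))
    }
    groups[[paste(u, collapse = "+")]] <- unique(unlist(clades[u]))
  }
  pres <- presence_by_allele(counts)
  focal_keys <- pres$key[pres$lineage == focal]
  nonfocal <- pres[pres$lineage != focal, ]
  rows <- imap(groups, function(members, label) {
    inside <- unique(nonfocal$key[nonfocal$lineage %in% members])
    shared <- intersect(focal_keys, inside)
    outside <- unique(nonfocal$key[!nonfocal$lineage %in% members])
    tibble(group = label, n_shared = length(shared),
           n_exclusive = length(setdiff(shared, outside)))
  })
  list_rbind(rows)
}

new_sharing_report <- function(rows, focal, focal_total, focal_private,
                               digits) {
  denominator <- focal_total - focal_private
  rows$pct_shared <- pct_of(rows$n_shared, denominator, digits)
  rows$pct_exclusive <- pct_of(rows$n_exclusive, denominator, digits)
  rows <- rows[order(match(rows$type, c("lineage", "clade", "union")),
                     -rows$n_shared, -rows$n_exclusive, rows$group), ]
  rows <- rows[c("group", "type", "n_shared", "pct_shared",
                 "n_exclusive", "pct_exclusive")]
  structure(rows,
            focal = focal, focal_total = focal_total,
            focal_private = focal_private, denominator = denominator,
            digits = digits,
            class = c("sharing_report", class(tibble())))
}

#' Allele-sharing report
#'
#' Computes the full sharing summary for the focal lineage: per-lineage and
#' per-clade (and clade-union) shared and exclusively shared allele counts
#' with percentages of the focal lineage's non-private alleles
#' (denominator = focal total - focal private), half-up rounded.
#'
#' @param counts An [build_allele_counts()] table.
#' @param clades,unions As in [clade_sharing()]; clade rows are omitted when
#'   no clade definitions exist.
#' @param digits Decimal places for percentages (default 2).
#' @return A `sharing_report` tibble with columns `group`, `type`,
#'   `n_shared`, `pct_shared`, `n_exclusive`, `pct_exclusive`, rows sorted
#'   by shared count (descending) within type, and attributes `focal`,
#'   `focal_total`, `focal_private`, `denominator`.  When the denominator is
#'   zero the percentages are `NA` (undefined), not an error.
#' @export
sharing_report <- function(counts, clades = NULL, unions = NULL, digits = 2) {
  totals <- focal_totals(counts)
  sh <- shared_alleles(counts)
  ex <- exclusively_shared(counts)
  rows <- tibble(group = sh$lineage, type = "lineage", n_shared = sh$n_shared,
                 n_exclusive = ex$n_exclusive[match(sh$lineage, ex$lineage)])
  clades <- clades %||% attr(counts, "clades")
  if (!is.null(clades) && length(clades) > 0) {
    cl <- clade_sharing(counts, clades = clades, unions = unions)
    cl$type <- ifelse(grepl("+", cl$group, fixed = TRUE), "union", "clade")
    rows <- bind_rows(rows, cl[c("group", "type", "n_shared", "n_exclusive")])
  }
  new_sharing_report(rows, counts_focal(counts), totals$total,
                     totals$private, digits)
}

#' Sharing report from externally supplied counts
#'
#' Builds a `sharing_report` directly from printed or otherwise precomputed
#' shared/exclusive counts and focal totals -- useful to recompute published
#' percentage tables from their integer counts.
#'
#' @param rows Tibble with columns `group`, `n_shared` and optionally
#'   `n_exclusive` and `type` (default `"lineage"`).
#' @param focal_total Total number of alleles observed in the focal lineage.
#' @param focal_private Number of those private to it.
#' @param focal Focal label (cosmetic).
#' @param digits Decimal places for percentages.
#' @return A `sharing_report`, as from [sharing_report()].
#' @export
sharing_report_from_counts <- function(rows, focal_total, focal_private,
                                       focal = "focal", digits = 2) {
  rows <- as_tibble(rows)
  if (!all(c("group", "n_shared") %in% names(rows))) {
    ps_input_error("rows must have columns `group` and `n_shared`")
  }
  if (!"n_exclusive" %in% names(rows)) rows$n_exclusive <- NA_integer_
  if (!"type" %in% names(rows)) rows$type <- "lineage"
  new_sharing_report(rows, focal, focal_total, focal_private, digits)
}

#' Rank candidate parent lineages
#'
#' Orders the non-focal lineages of a sharing report by shared allele count
#' (descending), breaking ties by exclusively shared count and then by
#' label.  Under an allopolyploid origin the two top-ranked lineages are the
#' best nuclear-genome candidates for (or closest relatives of) the two
#' parents.
#'
#' @param report A [sharing_report()].
#' @return The lineage rows with a `rank` column, best candidate first.
#' @export
rank_parent_candidates <- function(report) {
  rows <- as_tibble(report)
  rows <- rows[rows$type == "lineage", , drop = FALSE]
  ex <- replace_na(rows$n_exclusive, 0L)
  rows <- rows[order(-rows$n_shared, -ex, rows$group), , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rows
}

#' @export
print.sharing_report <- function(x, ...) {
  cat(sprintf(
    "Allele sharing with focal lineage `%s`: %d private of %d alleles (denominator %d)\n",
    attr(x, "focal"), attr(x, "focal_private"), attr(x, "focal_total"),
    attr(x, "denominator")
  ))
  print(as_tibble(x), ...)
  invisible(x)
}

#' @export
tidy.sharing_report <- function(x, ...) as_tibble(x)

#' @export
glance.sharing_report <- function(x, ...) {
  tibble(
    focal = attr(x, "focal"),
    focal_total = attr(x, "focal_total"),
    focal_private = attr(x, "focal_private"),
    denominator = attr(x, "denominator"),
    n_lineages = sum(x$type == "lineage"),
    n_clades = sum(x$type == "clade")
  )
}

#' @export
autoplot.sharing_report <- function(object, ...) {
  rows <- as_tibble(object)
  rows <- rows[rows$type == "lineage", ]
  rows$group <- factor(rows$group, levels = rev(rows$group))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$pct_shared, y = .data$group)) +
    ggplot2::geom_col(fill = "#4c72b0") +
    ggplot2::labs(
      x = "% of focal non-private alleles shared", y = NULL,
      title = sprintf("Allele sharing with %s", attr(object, "focal"))
    ) +
    ggplot2::theme_minimal()
}

#' Serialise a sharing report
#'
#' @param report A [sharing_report()].
#' @param path Output TSV path.
#' @param provenance Optional extra `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_sharing_report <- function(report, path, provenance = NULL) {
  hdr <- c(
    if (!is.null(provenance)) paste0("# ", provenance),
    sprintf("# focal=%s private=%d total=%d denominator=%d",
            attr(report, "focal"), attr(report, "focal_private"),
            attr(report, "focal_total"), attr(report, "denominator"))
  )
  body <- utils::capture.output(
    utils::write.table(as.data.frame(report), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  )
  write_lines_plain(c(hdr, body), path)
  invisible(path)
}

#' Render a sharing report as a markdown table
#'
#' @param report A [sharing_report()].
#' @return Character vector of markdown lines (focal summary plus table).
#' @export
format_sharing_md <- function(report) {
  rows <- as_tibble(report)
  fmt_pct <- function(p) ifelse(is.na(p), "NA", sprintf("(%.2f%%)", p))
  c(
    sprintf("Focal lineage `%s`: %d private of %d alleles.",
            attr(report, "focal"), attr(report, "focal_private"),
            attr(report, "focal_total")),
    "",
    "| Group | Type | Shared | Exclusively shared |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %s %s | %s %s |",
            rows$group, rows$type,
            format(rows$n_shared, big.mark = ","), fmt_pct(rows$pct_shared),
            ifelse(is.na(rows$n_exclusive), "NA",
                   format(rows$n_exclusive, big.mark = ",")),
            fmt_pct(rows$pct_exclusive))
  )
}
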