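#' Variant filter configuration
#'
#' Bundles the thresholds of the post-clustering GBS filter cascade: indel
#' removal, minor-allele-frequency floor, a closed read-depth window
#' (vcftools `--min-meanDP`/`--max-meanDP` semantics), a minimum number of
#' genotyped samples per site, and the focal-informativeness rules that keep
#' only sites able to discriminate the parentage of the focal lineage.
#'
#' @param maf_min Minimum minor allele frequency in `[0, 0.5]`, computed over
#'   known allele copies only.  Default 0.02.
#' @param depth_min,depth_max Closed depth window; sites (or genotypes, see
#'   `depth_mode`) with depth in `[depth_min, depth_max]` are kept.
#'   Defaults 10 and 300.
#' @param depth_mode `"site_mean"` filters whole sites on their mean known
#'   call depth (falling back to the site-level `INFO/DP`); `"genotype"`
#'   masks individual calls outside the window to MISSING and then drops
#'   empty sites.
#' @param min_samples_per_site Minimum number of non-missing calls a site
#'   must retain.  Default 40 (of the study-scale 210 samples).
#' @param focal_min_carriers Minimum number of focal samples that must carry
#'   a non-reference allele at the site.  Default 3 (of the 9 focal
#'   individuals at study scale).
#' @param carrier_mode `"individuals"` counts carrier samples (default);
#'   `"copies"` counts non-reference allele copies instead.
#' @param drop_ubiquitous Drop sites whose non-reference alleles are carried
#'   in every lineage (such sites cannot discriminate parentage).
#' @param require_focal_presence Drop sites at which no focal sample has a
#'   call.
#' @return A `filter_config` list.
#' @export
filter_config <- function(maf_min = 0.02,
                          depth_min = 10,
                          depth_max = 300,
                          depth_mode = c("site_mean", "genotype"),
                          min_samples_per_site = 40,
                          focal_min_carriers = 3,
                          carrier_mode = c("individuals", "copies"),
                          drop_ubiquitous = TRUE,
                          require_focal_presence = TRUE) {
  depth_mode <- match.arg(depth_mode)
  carrier_mode <- match.arg(carrier_mode)
  if (maf_min < 0 || maf_min > 0.5) ps_input_error("maf_min must be in [0, 0.5]")
  if (depth_min > depth_max) ps_input_error("depth_min must be <= depth_max")
  if (depth_min < 0 || min_samples_per_site < 0 || focal_min_carriers < 0) {
    ps_input_error("filter thresholds must be non-negative")
  }
  structure(
    list(
      maf_min = maf_min, depth_min = depth_min, depth_max = depth_max,
      depth_mode = depth_mode, min_samples_per_site = min_samples_per_site,
      focal_min_carriers = focal_min_carriers, carrier_mode = carrier_mode,
      drop_ubiquitous = drop_ubiquitous,
      require_focal_presence = require_focal_presence
    ),
    class = "filter_config"
  )
}

#' Remove indel records
#'
#' Keeps only sites where every allele (reference and alternates) is a single
#' nucleotide; variant order is preserved.
#'
#' @param geno A genotype tibble.
#' @return The filtered genotype tibble.
#' @export
remove_indels <- function(geno) {
  vt <- variant_tbl(geno)
  alt <- split_alt(vt$alt)
  is_indel <- nchar(vt$ref) != 1L |
    map_lgl(alt, function(a) any(nchar(a) != 1L))
  keep_variants(geno, paste(vt$locus, vt$pos)[!is_indel])
}

# per-variant allele copy counts over known calls
site_allele_counts <- function(geno) {
  copies <- tibble(
    locus = c(geno$locus, geno$locus),
    pos = c(geno$pos, geno$pos),
    allele = c(geno$a1, geno$a2)
  )
  copies <- copies[!is.na(copies$allele), , drop = FALSE]
  count(copies, .data$locus, .data$pos, .data$allele, name = "n_copies")
}

#' Filter on minor allele frequency
#'
#' The minor allele frequency of a site is the frequency of its second most
#' frequent allele among known allele copies (missing calls contribute
#' nothing to the denominator).  Sites with MAF below `maf_min`, including
#' monomorphic sites and sites with zero known copies, are removed.
#'
#' @param geno A genotype tibble.
#' @param maf_min MAF floor; the comparison is `>=`.
#' @return The filtered genotype tibble.
#' @export
filter_maf <- function(geno, maf_min = 0.02) {
  if (nrow(geno) == 0) return(geno)
  ac <- site_allele_counts(geno)
  stats <- summarise(
    group_by(ac, .data$locus, .data$pos),
    maf = if (n() < 2) 0 else sort(.data$n_copies, decreasing = TRUE)[2] /
      sum(.data$n_copies),
    .groups = "drop"
  )
  keepers <- stats[stats$maf >= maf_min - 1e-9, c("locus", "pos")]
  # sites absent from `ac` have zero known copies and are always dropped
  keys <- variant_keys(geno)
  keep_variants(geno, intersect(keys, paste(keepers$locus, keepers$pos)))
}

#' Filter on read depth
#'
#' In `"site_mean"` mode the site depth is the mean of the known per-genotype
#' depths (or, when none is known, the site-level `INFO/DP`); sites whose
#' depth falls outside the closed window are removed, and sites with no depth
#' information at all are kept with a warning.  In `"genotype"` mode each
#' call with a known depth outside the window is masked to MISSING and sites
#' left with no calls are removed.
#'
#' @param geno A genotype tibble.
#' @param depth_min,depth_max Closed window bounds.
#' @param depth_mode `"site_mean"` or `"genotype"`.
#' @return The filtered genotype tibble.
#' @export
filter_depth <- function(geno, depth_min = 10, depth_max = 300,
                         depth_mode = c("site_mean", "genotype")) {
  depth_mode <- match.arg(depth_mode)
  if (nrow(geno) == 0) return(geno)
  if (depth_mode == "site_mean") {
    stats <- summarise(
      group_by(as_tibble(geno), .data$locus, .data$pos),
      mean_dp = if (all(is.na(.data$dp))) .data$site_dp[1] else
        mean(.data$dp, na.rm = TRUE),
      .groups = "drop"
    )
    unknown <- is.na(stats$mean_dp)
    if (any(unknown)) {
      warn(sprintf("%d site(s) have no depth information; kept", sum(unknown)))
    }
    keep <- unknown | (stats$mean_dp >= depth_min & stats$mean_dp <= depth_max)
    keep_variants(geno, paste(stats$locus, stats$pos)[keep])
  } else {
    mask <- !is.na(geno$dp) & !is.na(geno$a1) &
      (geno$dp < depth_min | geno$dp > depth_max)
    geno$a1[mask] <- NA_integer_
    geno$a2[mask] <- NA_integer_
    attr(geno, "n_masked") <- sum(mask)
    filter_site_presence(geno, min_samples = 1)
  }
}

#' Filter on per-site genotyping rate
#'
#' Keeps sites genotyped (non-missing call) in at least `min_samples`
#' samples.
#'
#' @param geno A genotype tibble.
#' @param min_samples Minimum number of non-missing calls.
#' @return The filtered genotype tibble.
#' @export
filter_site_presence <- function(geno, min_samples = 40) {
  if (nrow(geno) == 0) return(geno)
  n_masked <- attr(geno, "n_masked")
  stats <- summarise(
    group_by(as_tibble(geno), .data$locus, .data$pos),
    n_called = sum(!is.na(.data$a1)),
    .groups = "drop"
  )
  out <- keep_variants(
    geno, paste(stats$locus, stats$pos)[stats$n_called >= min_samples]
  )
  attr(out, "n_masked") <- n_masked
  out
}

#' Keep only sites informative about the focal lineage
#'
#' Applies up to three rules, each switchable: (a) at least
#' `focal_min_carriers` focal samples (or allele copies, see `carrier_mode`)
#' carry a non-reference allele of the site; (b) the site's non-reference
#' alleles are *not* carried in every lineage (a ubiquitous variant cannot
#' discriminate parentage); (c) at least one focal sample has a non-missing
#' call.
#'
#' @param geno A genotype tibble.
#' @param pm A popmap covering the table's samples.
#' @param focal_min_carriers,carrier_mode,drop_ubiquitous,require_focal_presence
#'   See [filter_config()].
#' @param focal Focal lineage label; defaults to the popmap's.
#' @return The filtered genotype tibble.
#' @export
focal_informative_filter <- function(geno, pm,
                                     focal_min_carriers = 3,
                                     carrier_mode = c("individuals", "copies"),
                                     drop_ubiquitous = TRUE,
                                     require_focal_presence = TRUE,
                                     focal = focal_lineage(pm)) {
  carrier_mode <- match.arg(carrier_mode)
  if (nrow(geno) == 0) return(geno)
  lin <- pm$lineage[match(geno$sample, pm$sample)]
  if (any(is.na(lin))) {
    ps_input_error("popmap does not cover all samples in the genotype table")
  }
  if (!any(lin == focal)) {
    ps_input_error(paste0("focal lineage `", focal,
                          "` has no samples in the genotype table"))
  }
  g <- as_tibble(geno)
  g$lineage <- lin
  g$carrier <- !is.na(g$a1) & (g$a1 > 0L | g$a2 > 0L)
  g$n_alt_copies <- (!is.na(g$a1)) * ((g$a1 > 0L) + (g$a2 > 0L))

  focal_stats <- summarise(
    group_by(g[g$lineage == focal, ], .data$locus, .data$pos),
    n_carrier = sum(.data$carrier),
    n_copies = sum(.data$n_alt_copies),
    n_called = sum(!is.na(.data$a1)),
    .groups = "drop"
  )
  lin_carrier <- summarise(
    group_by(g, .data$locus, .data$pos, .data$lineage),
    carrier = any(.data$carrier), .groups = "drop"
  )
  n_lineages <- length(unique(lin))
  ubiq <- summarise(
    group_by(lin_carrier, .data$locus, .data$pos),
    ubiquitous = sum(.data$carrier) == n_lineages, .groups = "drop"
  )

  vt <- variant_tbl(geno)
  key <- paste(vt$locus, vt$pos)
  fs <- focal_stats[match(key, paste(focal_stats$locus, focal_stats$pos)), ]
  ub <- ubiq$ubiquitous[match(key, paste(ubiq$locus, ubiq$pos))]
  carriers <- if (carrier_mode == "individuals") fs$n_carrier else fs$n_copies
  keep <- carriers >= focal_min_carriers
  if (drop_ubiquitous) keep <- keep & !ub
  if (require_focal_presence) keep <- keep & fs$n_called >= 1L
  keep_variants(geno, key[keep])
}

#' Apply the full filter cascade
#'
#' Runs, in order: indel removal, MAF, depth, site presence, and the
#' focal-informativeness rules, and attaches a per-stage log (retrievable
#' with [filter_log()]) in which `n_in - n_removed = n_out` holds per stage
#' and consecutive stages chain.
#'
#' @param geno A genotype tibble.
#' @param pm A popmap (required for the focal stage; with `NULL` the focal
#'   stage is skipped).
#' @param config A [filter_config()].
#' @return The filtered genotype tibble with a `"filter_log"` attribute.
#' @export
apply_filter_cascade <- function(geno, pm = NULL, config = filter_config()) {
  stages <- list(
    indels = function(g) remove_indels(g),
    maf = function(g) filter_maf(g, config$maf_min),
    depth = function(g) filter_depth(g, config$depth_min, config$depth_max,
                                     config$depth_mode),
    presence = function(g) filter_site_presence(g, config$min_samples_per_site),
    focal = function(g) focal_informative_filter(
      g, pm,
      focal_min_carriers = config$focal_min_carriers,
      carrier_mode = config$carrier_mode,
      drop_ubiquitous = config$drop_ubiquitous,
      require_focal_presence = config$require_focal_presence
    )
  )
  if (is.null(pm)) stages$focal <- NULL
  log <- vector("list", length(stages))
  current <- geno
  for (k in seq_along(stages)) {
    n_in <- n_variants(current)
    current <- stages[[k]](current)
    n_out <- n_variants(current)
    log[[k]] <- tibble(
      stage = names(stages)[k], n_in = n_in, n_out = n_out,
      n_removed = n_in - n_out,
      n_genotypes_masked = attr(current, "n_masked") %||% 0L
    )
    attr(current, "n_masked") <- NULL
  }
  attr(current, "filter_log") <- list_rbind(log)
  current
}

#' @describeIn apply_filter_cascade Retrieve the per-stage filter log of a
#'   cascade result.
#' @param x A genotype tibble returned by `apply_filter_cascade()`.
#' @export
filter_log <- function(x) {
  attr(x, "filter_log") %||%
    ps_input_error("no filter log attached; run apply_filter_cascade() first")
}

#' Read a filter configuration from a YAML or key=value file
#'
#' @param path Path to a YAML file (or flat `key: value` file) whose keys
#'   match the arguments of [filter_config()].
#' @return A `filter_config`.
#' @export
read_filter_config <- function(path) {
  if (!file.exists(path)) ps_input_error(paste0("no such file: ", path))
  vals <- tryCatch(yaml::read_yaml(path), error = function(e) {
    ps_input_error(paste0("malformed config file ", path, ": ",
                          conditionMessage(e)))
  })
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(filter_config)))
  if (length(unknown)) {
    ps_input_error(paste0("unknown filter config key(s): ",
                          paste(unknown, collapse = ", ")))
  }
  do.call(filter_config, vals)
}
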