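#' Simulation configuration
#'
#' Describes a GBS-like SNP dataset with the hierarchical population
#' structure the sharing analysis assumes: diploid lineages diverging
#' within clades under a Balding-Nichols drift model, one allotetraploid
#' focal lineage formed from two parent lineages with disomic inheritance
#' (a fixed 2+2 subgenome contribution per sample, exported as a
#' pseudo-diploid presence call, as diploid genotype calling of tetraploid
#' GBS reads would), optional clonal ramets with a per-site error rate,
#' uniform missingness, negative-binomial read depths, and optionally a
#' fraction of indel records to exercise the filters.
#'
#' Per locus, the ancestral allele frequency p is drawn uniformly from
#' `ancestral_freq_range`; each clade frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = f_clade`; each lineage
#' frequency likewise around its clade frequency with `F = f_lineage`.
#' Diploid genotypes are `Binomial(2, lineage frequency)`.
#'
#' @param n_loci Number of biallelic SNP loci.
#' @param clades Named list clade -> lineage labels.  Default: three clades
#'   of 3, 4 and 2 diploid lineages.
#' @param samples_per_lineage Integer, or named vector per lineage.
#' @param focal Label of the allotetraploid focal lineage.
#' @param parents Two distinct simulated lineages contributing the focal
#'   subgenomes.
#' @param n_focal_samples Number of focal samples (default 9, the study
#'   scale of the focal taxon).
#' @param f_clade,f_lineage Divergence (drift) parameters in `(0, 1)`.
#' @param ancestral_freq_range Interval within `(0, 1)`.
#' @param clone_spec List of `list(lineage =, n_ramets =, error_rate =)`
#'   entries; ramets copy the lineage's first sample with independent
#'   per-site error (a resampled genotype).
#' @param missing_rate Fraction of calls masked to MISSING.
#' @param depth_mean,depth_dispersion Negative-binomial depth model (mu and
#'   size).
#' @param indel_rate Fraction of loci converted to indel records.
#' @param seed Integer seed; identical configs give identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_loci = 5000,
                       clades = list(
                         cladeI = c("L1", "L2", "L3"),
                         cladeII = c("L4", "L5", "L6", "L7"),
                         cladeIII = c("L8", "L9")
                       ),
                       samples_per_lineage = 8,
                       focal = "allo4x",
                       parents = c("L1", "L4"),
                       n_focal_samples = 9,
                       f_clade = 0.15,
                       f_lineage = 0.05,
                       ancestral_freq_range = c(0.05, 0.95),
                       clone_spec = list(),
                       missing_rate = 0.2,
                       depth_mean = 50,
                       depth_dispersion = 5,
                       indel_rate = 0,
                       seed = 1L) {
  lineages <- unlist(clades, use.names = FALSE)
  if (n_loci <= 0) ps_input_error("n_loci must be positive")
  if (anyDuplicated(lineages)) ps_input_error("lineage labels must be unique")
  if (length(parents) != 2 || parents[1] == parents[2]) {
    ps_input_error("exactly two distinct parent lineages are required")
  }
  if (!all(parents %in% lineages)) {
    ps_input_error("parent lineage absent from the simulated clades")
  }
  if (focal %in% lineages) ps_input_error("focal label collides with a lineage")
  for (r in c(missing_rate, indel_rate)) {
    if (r < 0 || r > 1) ps_input_error("rates must be in [0, 1]")
  }
  for (f in c(f_clade, f_lineage)) {
    if (f <= 0 || f >= 1) ps_input_error("divergence parameters must be in (0, 1)")
  }
  if (length(ancestral_freq_range) != 2 || ancestral_freq_range[1] <= 0 ||
      ancestral_freq_range[2] >= 1 ||
      ancestral_freq_range[1] > ancestral_freq_range[2]) {
    ps_input_error("ancestral_freq_range must be an interval within (0, 1)")
  }
  if (length(samples_per_lineage) == 1 && is.null(names(samples_per_lineage))) {
    samples_per_lineage <- setNames(rep(as.integer(samples_per_lineage),
                                        length(lineages)), lineages)
  }
  if (!all(lineages %in% names(samples_per_lineage))) {
    ps_input_error("samples_per_lineage must cover every lineage")
  }
  for (cs in clone_spec) {
    if (!all(c("lineage", "n_ramets", "error_rate") %in% names(cs))) {
      ps_input_error("each clone_spec entry needs lineage, n_ramets, error_rate")
    }
    if (!cs$lineage %in% c(lineages, focal)) {
      ps_input_error(paste0("clone_spec lineage not simulated: ", cs$lineage))
    }
    if (cs$error_rate < 0 || cs$error_rate > 1) {
      ps_input_error("clone error_rate must be in [0, 1]")
    }
  }
  structure(
    list(
      n_loci = as.integer(n_loci), clades = clades,
      samples_per_lineage = samples_per_lineage, focal = focal,
      parents = parents, n_focal_samples = as.integer(n_focal_samples),
      f_clade = f_clade, f_lineage = f_lineage,
      ancestral_freq_range = ancestral_freq_range, clone_spec = clone_spec,
      missing_rate = missing_rate, depth_mean = depth_mean,
      depth_dispersion = depth_dispersion, indel_rate = indel_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

balding_nichols <- function(p, f) {
  shape1 <- p * (1 - f) / f
  shape2 <- (1 - p) * (1 - f) / f
  rbeta(length(p), shape1, shape2)
}

#' Simulate a GBS-like SNP dataset with known truth
#'
#' Draws the dataset described by a [sim_config()]: genotypes for every
#' diploid lineage, pseudo-diploid calls for the allotetraploid focal
#' lineage (two allele copies from each parent's frequency; heterozygous
#' whenever both states occur among the four copies), clonal ramets,
#' missingness and depths.  All randomness flows from `config$seed`;
#' identical configs give identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (genotype tibble), `popmap`,
#'   and `truth` -- a list holding the true `parents`, `clone_pairs`
#'   (tibble `sample_a`, `sample_b`, `lineage`), per-locus per-lineage
#'   allele frequencies (`lineage_freqs`), the focal subgenome dosage
#'   matrices, injected `indel_variants`, and the seed.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  n <- config$n_loci
  clades <- config$clades
  lineages <- unlist(clades, use.names = FALSE)
  clade_of <- setNames(rep(names(clades), lengths(clades)), lineages)

  p_anc <- runif(n, config$ancestral_freq_range[1], config$ancestral_freq_range[2])
  p_clade <- vapply(names(clades), function(cl) balding_nichols(p_anc, config$f_clade),
                    numeric(n))
  p_lin <- vapply(lineages, function(l) {
    balding_nichols(p_clade[, clade_of[[l]]], config$f_lineage)
  }, numeric(n))

  samples <- character(0)
  sample_lineage <- character(0)
  alt_copies <- NULL  # loci x samples matrix, diploid 0..2, focal 0..4
  ploidy <- integer(0)

  for (l in lineages) {
    k <- config$samples_per_lineage[[l]]
    if (k == 0) next
    g <- matrix(rbinom(n * k, 2L, p_lin[, l]), nrow = n)
    ids <- sprintf("%s_s%d", l, seq_len(k))
    samples <- c(samples, ids)
    sample_lineage <- c(sample_lineage, rep(l, k))
    ploidy <- c(ploidy, rep(2L, k))
    alt_copies <- cbind(alt_copies, g)
  }

  kf <- config$n_focal_samples
  pA <- p_lin[, config$parents[1]]
  pB <- p_lin[, config$parents[2]]
  dosage_a <- matrix(rbinom(n * kf, 2L, pA), nrow = n)
  dosage_b <- matrix(rbinom(n * kf, 2L, pB), nrow = n)
  focal_ids <- sprintf("%s_s%d", config$focal, seq_len(kf))
  samples <- c(samples, focal_ids)
  sample_lineage <- c(sample_lineage, rep(config$focal, kf))
  ploidy <- c(ploidy, rep(4L, kf))
  alt_copies <- cbind(alt_copies, dosage_a + dosage_b)
  colnames(alt_copies) <- samples

  # clonal ramets: copy a progenitor column, resampling sites independently
  # at the error rate from the progenitor's generating model
  clone_pairs <- list()
  for (cs in config$clone_spec) {
    members <- samples[sample_lineage == cs$lineage]
    prog <- members[1]
    is_focal <- cs$lineage == config$focal
    for (r in seq_len(cs$n_ramets)) {
      id <- sprintf("%s_ramet%d", prog, r)
      col <- alt_copies[, prog]
      err <- runif(n) < cs$error_rate
      if (any(err)) {
        col[err] <- if (is_focal) {
          rbinom(sum(err), 2L, pA[err]) + rbinom(sum(err), 2L, pB[err])
        } else {
          rbinom(sum(err), 2L, p_lin[err, cs$lineage])
        }
      }
      alt_copies <- cbind(alt_copies, col)
      colnames(alt_copies)[ncol(alt_copies)] <- id
      samples <- c(samples, id)
      sample_lineage <- c(sample_lineage, cs$lineage)
      ploidy <- c(ploidy, if (is_focal) 4L else 2L)
    }
    group <- c(prog, sprintf("%s_ramet%d", prog, seq_len(cs$n_ramets)))
    prs <- combn(group, 2)
    clone_pairs[[length(clone_pairs) + 1]] <- tibble(
      sample_a = prs[1, ], sample_b = prs[2, ], lineage = cs$lineage
    )
  }
  clone_pairs <- if (length(clone_pairs)) list_rbind(clone_pairs) else
    tibble(sample_a = character(0), sample_b = character(0),
           lineage = character(0))

  n_samples <- length(samples)
  max_copies <- matrix(rep(ploidy, each = n), nrow = n)
  a1 <- ifelse(alt_copies == 0L, 0L, ifelse(alt_copies == max_copies, 1L, 0L))
  a2 <- ifelse(alt_copies == 0L, 0L, 1L)

  miss <- matrix(runif(n * n_samples) < config$missing_rate, nrow = n)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  dp <- matrix(rnbinom(n * n_samples, mu = config$depth_mean,
                       size = config$depth_dispersion), nrow = n)
  dp[miss] <- NA_integer_

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- map_chr(ref, function(r) sample(setdiff(bases, r), 1))
  indel_idx <- integer(0)
  if (config$indel_rate > 0) {
    n_indel <- round(config$indel_rate * n)
    indel_idx <- sort(sample.int(n, n_indel))
    alt[indel_idx] <- paste0(alt[indel_idx], "A")
  }
  locus <- sprintf("loc%05d", seq_len(n))
  pos <- sample.int(120L, n, replace = TRUE)

  geno <- geno_tbl(tibble(
    locus = rep(locus, each = n_samples),
    pos = rep(pos, each = n_samples),
    ref = rep(ref, each = n_samples),
    alt = rep(alt, each = n_samples),
    sample = rep(samples, times = n),
    a1 = as.vector(t(a1)),
    a2 = as.vector(t(a2)),
    dp = as.vector(t(dp)),
    site_dp = NA_real_
  ))

  pm <- popmap(
    tibble(
      sample = samples, lineage = sample_lineage,
      clade = unname(clade_of[sample_lineage])
    ),
    focal = config$focal
  )

  dimnames(p_lin) <- list(paste(locus, pos), lineages)
  truth <- structure(
    list(
      focal = config$focal,
      parents = config$parents,
      clone_pairs = clone_pairs,
      lineage_freqs = p_lin,
      ancestral_freqs = p_anc,
      focal_dosage = list(a = dosage_a, b = dosage_b),
      indel_variants = tibble(locus = locus[indel_idx], pos = pos[indel_idx]),
      seed = config$seed
    ),
    class = "sim_truth"
  )
  list(genotypes = geno, popmap = pm, truth = truth)
}

#' Inject GBS-like artifacts into a genotype table
#'
#' Converts a known fraction of variants into indel records (alternate
#' alleles lengthened to 2 bp), masks calls to MISSING at a given rate, and
#' optionally overwrites per-genotype depths from a negative-binomial model
#' -- producing exactly the inputs the filter cascade is meant to clean,
#' together with the truth of what was injected.
#'
#' @param geno A genotype tibble.
#' @param indel_rate Fraction of variants converted (count =
#'   `round(indel_rate * n_variants)`).
#' @param missing_rate Per-call masking probability.
#' @param depth_model Optional `list(mean =, dispersion =)`.
#' @param seed Optional integer seed for reproducibility.
#' @return A list: `genotypes` (modified table) and `artifacts` (a list with
#'   `indel_variants` tibble, `n_masked`, and the depth model used).
#' @export
inject_artifacts <- function(geno, indel_rate = 0, missing_rate = 0,
                             depth_model = NULL, seed = NULL) {
  for (r in c(indel_rate, missing_rate)) {
    if (r < 0 || r > 1) ps_input_error("rates must be in [0, 1]")
  }
  run <- function() {
    vt <- variant_tbl(geno)
    keys <- paste(vt$locus, vt$pos)
    n_indel <- round(indel_rate * nrow(vt))
    idx <- if (n_indel > 0) sort(sample.int(nrow(vt), n_indel)) else integer(0)
    if (length(idx)) {
      new_alt <- map_chr(split_alt(vt$alt[idx]), function(a) {
        paste(paste0(a, "A"), collapse = ",")
      })
      lut <- setNames(new_alt, keys[idx])
      gkey <- paste(geno$locus, geno$pos)
      hit <- gkey %in% keys[idx]
      geno$alt[hit] <- lut[gkey[hit]]
    }
    n_masked <- 0L
    if (missing_rate > 0) {
      mask <- runif(nrow(geno)) < missing_rate
      geno$a1[mask] <- NA_integer_
      geno$a2[mask] <- NA_integer_
      n_masked <- sum(mask)
    }
    if (!is.null(depth_model)) {
      known <- !is.na(geno$a1)
      geno$dp <- NA_integer_
      geno$dp[known] <- rnbinom(sum(known), mu = depth_model$mean,
                                size = depth_model$dispersion)
    }
    geno$dp[is.na(geno$a1)] <- NA_integer_
    list(
      genotypes = geno,
      artifacts = list(
        indel_variants = tibble(locus = vt$locus[idx], pos = vt$pos[idx]),
        n_masked = n_masked,
        depth_model = depth_model
      )
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Write / read the truth record of a simulation
#'
#' Serialises the compact part of a [simulate_dataset()] truth (focal label,
#' parent pair, clone pairs, injected indels, seed) as YAML.  The per-locus
#' frequency and dosage matrices stay in memory only.
#'
#' @param truth A `sim_truth` list.
#' @param path Output path.
#' @return `path` invisibly, or for `read_truth` the truth list.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(
    list(
      focal = truth$focal,
      parents = as.list(truth$parents),
      clone_pairs = if (nrow(truth$clone_pairs)) {
        apply(truth$clone_pairs, 1, as.list, simplify = FALSE)
      } else {
        list()
      },
      indel_variants = if (nrow(truth$indel_variants)) {
        apply(truth$indel_variants, 1, as.list, simplify = FALSE)
      } else {
        list()
      },
      seed = truth$seed
    ),
    path
  )
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) ps_input_error(paste0("no such file: ", path))
  raw <- yaml::read_yaml(path)
  raw$parents <- unlist(raw$parents)
  raw$clone_pairs <- if (length(raw$clone_pairs)) {
    list_rbind(map(raw$clone_pairs, as_tibble))
  } else {
    tibble(sample_a = character(0), sample_b = character(0),
           lineage = character(0))
  }
  raw$indel_variants <- if (length(raw$indel_variants)) {
    mutate(list_rbind(map(raw$indel_variants, as_tibble)),
           pos = as.integer(.data$pos))
  } else {
    tibble(locus = character(0), pos = integer(0))
  }
  raw
}
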