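make_site <- function(locus, ref, alt, gts, dps = NULL, site_dp = NA_real_) {
  samples <- paste0("s", seq_along(gts))
  a <- do.call(rbind, lapply(strsplit(gts, "/"), function(x) {
    suppressWarnings(as.integer(x))
  }))
  tibble::tibble(
    locus = locus, pos = 1L, ref = ref, alt = alt, sample = samples,
    a1 = a[, 1], a2 = a[, 2],
    dp = if (is.null(dps)) NA_integer_ else as.integer(dps),
    site_dp = site_dp
  )
}

test_that("remove_indels drops exactly the sites with a non-SNP allele", {
  g <- geno_tbl(dplyr::bind_rows(
    make_site("snp", "A", "G", c("0/1", "0/0")),
    make_site("del", "AT", "A", c("0/1", "0/0")),
    make_site("mixed_ins", "A", "AT,G", c("0/1", "0/2"))
  ))
  out <- remove_indels(g)
  expect_equal(unique(out$locus), "snp")
  # all-SNP input is untouched
  snps <- geno_tbl(make_site("snp", "A", "G", c("0/1", "0/0")))
  expect_equal(as.data.frame(remove_indels(snps)), as.data.frame(snps))
})

test_that("MAF filter uses known copies and a closed >= boundary", {
  # 39:1 copies -> freq 0.025, kept at 0.02; 199:1 -> 0.005, removed
  gt_keep <- c(rep("0/0", 19), "0/1")            # 20 samples, copies 39:1
  gt_drop <- c(rep("0/0", 99), "0/1")            # 100 samples, copies 199:1
  g <- geno_tbl(dplyr::bind_rows(
    make_site("keep", "A", "G", gt_keep),
    make_site("mono", "C", "T", rep("0/0", 20))
  ))
  expect_equal(unique(filter_maf(g, 0.02)$locus), "keep")
  g2 <- geno_tbl(make_site("drop", "A", "G", gt_drop))
  expect_equal(nrow(filter_maf(g2, 0.02)), 0L)
  # missing calls are excluded from the denominator
  g3 <- geno_tbl(make_site("m", "A", "G", c("0/1", "./.", rep("0/0", 18))))
  expect_equal(unique(filter_maf(g3, 0.02)$locus), "m")  # 1/38 = 0.026
  # a site with zero known copies is always removed
  g4 <- geno_tbl(make_site("allmiss", "A", "G", c("./.", "./.")))
  expect_equal(nrow(filter_maf(g4, 0)), 0L)
})

test_that("site-mean depth window is closed: 9 out, 10 and 300 in, 301 out", {
  g <- geno_tbl(dplyr::bind_rows(
    make_site("d9", "A", "G", c("0/1", "0/0"), dps = c(9, 9)),
    make_site("d10", "A", "G", c("0/1", "0/0"), dps = c(10, 10)),
    make_site("d300", "A", "G", c("0/1", "0/0"), dps = c(300, 300)),
    make_site("d301", "A", "G", c("0/1", "0/0"), dps = c(301, 301))
  ))
  out <- filter_depth(g, 10, 300, "site_mean")
  expect_equal(unique(out$locus), c("d10", "d300"))
  # site-level INFO depth is the fallback when no call depths are known
  g2 <- geno_tbl(dplyr::bind_rows(
    make_site("siteinfo", "A", "G", c("0/1", "0/0"), site_dp = 5),
    make_site("sitein", "A", "G", c("0/1", "0/0"), site_dp = 50)
  ))
  expect_equal(unique(filter_depth(g2, 10, 300)$locus), "sitein")
  # no depth information at all: kept, with a warning
  g3 <- geno_tbl(make_site("nodepth", "A", "G", c("0/1", "0/0")))
  expect_warning(out3 <- filter_depth(g3, 10, 300), "no depth")
  expect_equal(as.data.frame(out3), as.data.frame(g3))
})

test_that("genotype-mode depth masks individual calls then drops empty sites", {
  g <- geno_tbl(make_site("m", "A", "G", c("0/1", "0/0", "1/1", "0/1"),
                          dps = c(5, 20, 30, 40)))
  out <- filter_depth(g, 10, 300, "genotype")
  expect_equal(n_variants(out), 1L)
  expect_true(is.na(out$a1[out$sample == "s1"]))
  expect_equal(out$a1[out$sample == "s3"], 1L)
  # all calls out of window -> site removed entirely
  g2 <- geno_tbl(make_site("gone", "A", "G", c("0/1", "0/0"), dps = c(2, 3)))
  expect_equal(nrow(filter_depth(g2, 10, 300, "genotype")), 0L)
})

test_that("site-presence filter keeps sites genotyped in >= min samples", {
  g <- geno_tbl(dplyr::bind_rows(
    make_site("one", "A", "G", c("0/1", "./.", "./.", "./.")),
    make_site("two", "C", "T", c("0/1", "0/0", "./.", "./."))
  ))
  expect_equal(unique(filter_site_presence(g, 2)$locus), "two")
  expect_equal(as.data.frame(filter_site_presence(g, 0)), as.data.frame(g))
})

test_that("focal-informativeness rules reproduce the F1 enumeration", {
  g <- f1_geno()
  pm <- f1_popmap()
  out <- focal_informative_filter(g, pm, focal_min_carriers = 1)
  expect_equal(unique(out$locus), c("v1", "v2", "v4"))
  # carrier minimum above what the focal panel can supply removes everything
  out3 <- focal_informative_filter(g, pm, focal_min_carriers = 3)
  expect_equal(nrow(out3), 0L)
  # copies mode: v3 has 4 focal alt copies (two 1/1), passes 3-copy rule
  outc <- focal_informative_filter(g, pm, focal_min_carriers = 3,
                                   carrier_mode = "copies",
                                   drop_ubiquitous = FALSE)
  expect_equal(unique(outc$locus), "v3")
  # a site with no focal call at all fails require_focal_presence
  g2 <- geno_tbl(dplyr::bind_rows(
    make_site("nofocal", "A", "G", c("./.", "./.", "0/1", "0/1"))
  ))
  g2$sample <- c("x1", "x2", "b1", "c1")
  g2 <- geno_tbl(g2)
  out2 <- focal_informative_filter(g2, pm, focal_min_carriers = 0,
                                   drop_ubiquitous = FALSE)
  expect_equal(nrow(out2), 0L)
  # focal lineage absent from the table is an input error
  g3 <- f1_geno()
  g3 <- geno_tbl(g3[g3$sample %in% c("b1", "c1"), ])
  expect_error(focal_informative_filter(g3, pm), "no samples")
})

test_that("every filter stage is idempotent", {
  stages <- list(
    function(g) remove_indels(g),
    function(g) filter_maf(g, 0.05),
    function(g) suppressWarnings(filter_depth(g, 10, 60, "site_mean")),
    function(g) filter_depth(g, 10, 60, "genotype"),
    function(g) filter_site_presence(g, 2),
    function(g) focal_informative_filter(g, rand_popmap(paste0("s", 1:6)),
                                         focal_min_carriers = 1)
  )
  for (seed in 1:4) {
    g <- rand_geno(15, paste0("s", 1:6), seed = seed)
    for (f in stages) {
      once <- f(g)
      twice <- f(once)
      expect_equal(geno_df(twice), geno_df(once))
    }
  }
})

test_that("the cascade equals manual composition of its stages in order", {
  pm <- rand_popmap(paste0("s", 1:8), n_lineages = 3)
  cfg <- filter_config(maf_min = 0.05, depth_min = 10, depth_max = 60,
                       min_samples_per_site = 3, focal_min_carriers = 1)
  for (seed in 1:5) {
    g <- rand_geno(25, paste0("s", 1:8), seed = seed)
    manual <- remove_indels(g)
    manual <- filter_maf(manual, 0.05)
    manual <- suppressWarnings(filter_depth(manual, 10, 60, "site_mean"))
    manual <- filter_site_presence(manual, 3)
    manual <- focal_informative_filter(manual, pm, focal_min_carriers = 1)
    casc <- suppressWarnings(apply_filter_cascade(g, pm, cfg))
    expect_equal(geno_df(casc), geno_df(manual))
  }
})

test_that("the filter log chains: in - removed = out across stages", {
  pm <- rand_popmap(paste0("s", 1:8), n_lineages = 3)
  g <- rand_geno(30, paste0("s", 1:8), seed = 11)
  out <- suppressWarnings(apply_filter_cascade(g, pm, filter_config(
    maf_min = 0.05, depth_min = 10, depth_max = 60,
    min_samples_per_site = 3, focal_min_carriers = 1
  )))
  log <- filter_log(out)
  expect_equal(log$stage, c("indels", "maf", "depth", "presence", "focal"))
  expect_equal(log$n_in - log$n_removed, log$n_out)
  expect_equal(log$n_in[-1], log$n_out[-nrow(log)])
  expect_equal(log$n_out[nrow(log)], n_variants(out))
})

test_that("a no-op configuration passes everything through unchanged", {
  g <- f1_geno()
  pm <- f1_popmap()
  cfg <- filter_config(maf_min = 0, depth_min = 0, depth_max = Inf,
                       min_samples_per_site = 0, focal_min_carriers = 0,
                       drop_ubiquitous = FALSE, require_focal_presence = FALSE)
  out <- apply_filter_cascade(g, pm, cfg)
  expect_equal(geno_df(out), geno_df(g))
  expect_true(all(filter_log(out)$n_removed == 0))
  # empty input: empty output, log of zeros
  empty <- g[0, ]
  out0 <- apply_filter_cascade(empty, NULL, cfg)
  expect_equal(nrow(out0), 0L)
  expect_true(all(filter_log(out0)$n_in == 0))
})

test_that("filter thresholds are validated", {
  expect_error(filter_config(maf_min = 0.7), "maf_min")
  expect_error(filter_config(depth_min = 50, depth_max = 10), "depth_min")
})
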