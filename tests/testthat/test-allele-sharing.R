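test_that("the F1 count table matches the hand enumeration", {
  counts <- build_allele_counts(f1_geno(), f1_popmap())
  # 8 (variant, allele) states observed somewhere
  states <- dplyr::distinct(tibble::as_tibble(counts), locus, pos, allele)
  expect_equal(nrow(states), 8L)
  # the focal-private state v4:1 is a single copy in lineage X only
  v4a1 <- counts[counts$locus == "v4" & counts$allele == 1L, ]
  expect_equal(v4a1$lineage, "X")
  expect_equal(v4a1$n_copies, 1L)
  # copy counts sum to the known copies of the matrix
  expect_equal(sum(counts$n_copies), sum(!is.na(f1_geno()$a1)) * 2L)
})

test_that("count table edge cases: single het sample, all-missing matrix", {
  pm <- popmap(tibble::tibble(sample = "s1", lineage = "P"), focal = "P")
  g <- geno_tbl(tibble::tibble(
    locus = "v", pos = 1L, ref = "A", alt = "G", sample = "s1",
    a1 = 0L, a2 = 1L
  ))
  counts <- build_allele_counts(g, pm)
  expect_equal(nrow(counts), 2L)
  expect_equal(counts$n_copies, c(1L, 1L))
  g$a1 <- NA_integer_
  g$a2 <- NA_integer_
  expect_equal(nrow(build_allele_counts(geno_tbl(g), pm)), 0L)
})

test_that("private / shared / exclusive on F1 match the enumeration", {
  counts <- build_allele_counts(f1_geno(), f1_popmap())
  priv <- private_alleles(counts)
  expect_equal(setNames(priv$n_private, priv$lineage),
               c(X = 1L, B = 0L, C = 0L))
  sh <- shared_alleles(counts)
  expect_equal(setNames(sh$n_shared, sh$lineage), c(B = 5L, C = 5L))
  ex <- exclusively_shared(counts)
  expect_equal(setNames(ex$n_exclusive, ex$lineage), c(B = 1L, C = 1L))
  # clade K1 = {B, C}: all six non-private focal alleles fall inside it
  cl <- clade_sharing(counts)
  expect_equal(cl$group, "K1")
  expect_equal(cl$n_shared, 6L)
  expect_equal(cl$n_exclusive, 6L)
})

test_that("sharing statistics equal the brute-force enumerator on random data", {
  samples <- paste0("s", 1:12)
  for (seed in 1:30) {
    g <- rand_geno(n_var = sample(3:20, 1), samples, seed = seed)
    pm <- rand_popmap(samples, n_lineages = 4, seed = seed)
    focal <- focal_lineage(pm)
    counts <- build_allele_counts(g, pm)
    priv <- private_alleles(counts)
    expect_equal(setNames(priv$n_private, priv$lineage)[unique(pm$lineage)],
                 oracle_private(g, pm)[unique(pm$lineage)])
    sh <- shared_alleles(counts)
    others <- setdiff(unique(pm$lineage), focal)
    expect_equal(setNames(sh$n_shared, sh$lineage)[others],
                 oracle_shared(g, pm, focal)[others])
    ex <- exclusively_shared(counts)
    expect_equal(setNames(ex$n_exclusive, ex$lineage)[others],
                 oracle_exclusive(g, pm, focal)[others])
    for (kl in names(lineage_clades(pm))) {
      members <- lineage_clades(pm)[[kl]]
      got <- clade_sharing(counts)
      expect_equal(
        c(shared = got$n_shared[got$group == kl],
          exclusive = got$n_exclusive[got$group == kl]),
        oracle_clade(g, pm, focal, members)
      )
    }
  }
})

test_that("degenerate sharing structures behave as defined", {
  # every allele in >= 2 lineages -> all private counts zero
  pm <- popmap(tibble::tibble(sample = c("a1", "b1"),
                              lineage = c("A", "B")), focal = "A")
  g <- geno_tbl(tibble::tibble(
    locus = "v", pos = 1L, ref = "A", alt = "G",
    sample = c("a1", "b1"), a1 = c(0L, 0L), a2 = c(1L, 1L)
  ))
  counts <- build_allele_counts(g, pm)
  expect_true(all(private_alleles(counts)$n_private == 0L))
  # a single lineage owns every allele
  pm1 <- popmap(tibble::tibble(sample = c("a1", "b1"), lineage = "A"),
                focal = "A")
  counts1 <- build_allele_counts(g, pm1)
  expect_equal(private_alleles(counts1)$n_private, 2L)
  # two identical lineages share symmetrically
  pm2 <- popmap(tibble::tibble(sample = c("a1", "b1", "c1"),
                               lineage = c("F", "B", "C")), focal = "F")
  g2 <- geno_tbl(tibble::tibble(
    locus = "v", pos = 1L, ref = "A", alt = "G",
    sample = c("a1", "b1", "c1"), a1 = 0L, a2 = 1L
  ))
  sh2 <- shared_alleles(build_allele_counts(g2, pm2))
  expect_equal(sh2$n_shared[1], sh2$n_shared[2])
})

test_that("clade unions merge members; focal membership is rejected", {
  counts <- build_allele_counts(f1_geno(), f1_popmap())
  # a singleton clade equals the per-lineage values
  single <- clade_sharing(counts, clades = list(onlyB = "B"))
  expect_equal(single$n_shared, 5L)
  expect_equal(single$n_exclusive, 1L)
  # the union of everything shares all non-private focal alleles exclusively
  both <- clade_sharing(counts, clades = list(k1 = "B", k2 = "C"),
                        unions = list(c("k1", "k2")))
  row <- both[both$group == "k1+k2", ]
  expect_equal(row$n_shared, 6L)
  expect_equal(row$n_exclusive, 6L)
  expect_error(clade_sharing(counts, clades = list(bad = c("X", "B"))),
               "focal")
  expect_error(clade_sharing(counts, clades = list(k1 = "B"),
                             unions = list(c("k1", "nope"))), "unknown clade")
})

test_that("report percentages use the non-private denominator, half-up", {
  rows <- tibble::tibble(group = c("a", "b"), n_shared = c(1L, 31L),
                         n_exclusive = c(0L, 1L))
  rep <- sharing_report_from_counts(rows, focal_total = 33, focal_private = 1)
  # denominator 32: 1/32 = 3.125% -> 3.13 under half-up (banker's gives 3.12)
  expect_equal(rep$pct_shared[rep$group == "a"], 3.13)
  expect_equal(rep$pct_shared[rep$group == "b"], 96.88)
  expect_equal(attr(rep, "denominator"), 32)
  # shared equal to the denominator is exactly 100%
  full <- sharing_report_from_counts(
    tibble::tibble(group = "a", n_shared = 32L), 33, 1)
  expect_equal(full$pct_shared, 100)
  # zero denominator: undefined percentages, no error
  none <- sharing_report_from_counts(
    tibble::tibble(group = "a", n_shared = 0L), 5, 5)
  expect_true(is.na(none$pct_shared))
})

test_that("the focal partition invariant holds on random tables", {
  samples <- paste0("s", 1:10)
  for (seed in 31:40) {
    g <- rand_geno(15, samples, seed = seed)
    pm <- rand_popmap(samples, n_lineages = 3, seed = seed)
    counts <- build_allele_counts(g, pm)
    rep <- sharing_report(counts)
    pres <- oracle_presence(g, pm)
    focal <- focal_lineage(pm)
    with_other <- sum(vapply(pres, function(l) {
      focal %in% l && length(l) > 1
    }, logical(1)))
    expect_equal(attr(rep, "focal_total"),
                 attr(rep, "focal_private") + with_other)
    # exclusive <= shared <= denominator on every row
    expect_true(all(rep$n_exclusive <= rep$n_shared))
    expect_true(all(rep$n_shared <= attr(rep, "denominator")))
  }
})

test_that("the F1 report carries the focal line `1 private of 7`", {
  rep <- sharing_report(build_allele_counts(f1_geno(), f1_popmap()))
  expect_equal(attr(rep, "focal_private"), 1L)
  expect_equal(attr(rep, "focal_total"), 7L)
  expect_output(print(rep), "1 private of 7")
  expect_equal(glance(rep)$denominator, 6L)
  expect_s3_class(tidy(rep), "tbl_df")
})

test_that("parent ranking orders by shared, then exclusive, then label", {
  # F1: B and C tie on both counts -> label order
  rep <- sharing_report(build_allele_counts(f1_geno(), f1_popmap()))
  rk <- rank_parent_candidates(rep)
  expect_equal(rk$group, c("B", "C"))
  # explicit tie-break on exclusive
  rows <- tibble::tibble(group = c("p", "q", "r"),
                         n_shared = c(10L, 10L, 9L),
                         n_exclusive = c(1L, 3L, 0L))
  rk2 <- rank_parent_candidates(sharing_report_from_counts(rows, 20, 2))
  expect_equal(rk2$group, c("q", "p", "r"))
  expect_equal(rk2$rank, 1:3)
})

test_that("hybrid lineages can be excluded before counting", {
  pm <- popmap(tibble::tibble(
    sample = c("x1", "b1", "h1"),
    lineage = c("X", "B", "HYB")
  ), focal = "X")
  g <- geno_tbl(tibble::tibble(
    locus = "v", pos = 1L, ref = "A", alt = "G",
    sample = c("x1", "b1", "h1"),
    a1 = c(0L, 0L, 1L), a2 = c(1L, 0L, 1L)
  ))
  all_in <- build_allele_counts(g, pm)
  expect_true("HYB" %in% all_in$lineage)
  # with the hybrid excluded, the alt allele becomes private to the focal
  no_hyb <- build_allele_counts(g, pm, exclude = "HYB")
  expect_false("HYB" %in% no_hyb$lineage)
  priv <- private_alleles(no_hyb)
  expect_equal(priv$n_private[priv$lineage == "X"], 1L)
  expect_error(build_allele_counts(g, pm, exclude = "X"), "focal")
})
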