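---
title: "Inferring allopolyploid origins from SNP allele sharing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring allopolyploid origins from SNP allele sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyshare)
```

polyshare answers two questions about a putatively allopolyploid plant
lineage from a genome-wide SNP matrix: *which lineages (or clades)
contributed its subgenomes?* and *is it propagating sexually or clonally?*
This vignette explains the statistics, the data model they operate on, the
tunable parameters, the synthetic-data model used to validate them, and the
numerical and design choices made where more than one defensible option
existed.

## Data model

The central container is a long tibble: one row per (variant, sample), with
the variant key `(locus, pos)` (GBS locus identifier and 1-based position
within it), the allele strings `ref` / `alt` (alternates comma-separated;
allele index 0 is the reference), the canonical unordered call `a1 <= a2`
(`NA`/`NA` for missing), the per-genotype read depth `dp`, and the
site-level depth `site_dp`. Two modelling commitments are baked in:

* **Genotypes are unordered multisets.** Phase is discarded on read
  (`0/1` and `1|0` are the same call) because every statistic here —
  allele counts, presence, shared heterozygosity — is phase-free.
* **Diploid calls only.** Half-calls (`0/.`) and non-diploid genotypes are
  converted to missing, with a warning. Diploid-called GBS data is the
  intended input; partial calls carry no usable information for shared
  heterozygosity and would make "heterozygous" ambiguous.

Multiallelic records are kept as single variants; each alternate is a
countable allele state of its site. An *allele* throughout means a
(site, allele-state) pair, and the reference allele is an allele like any
other — this is ordinary genpop semantics for count tables.

## The filter cascade

`apply_filter_cascade()` runs five stages in a fixed order — indel removal,
minor allele frequency, read depth, site presence, focal informativeness —
and logs variants in/out per stage. Defaults are the values a GBS study at
this scale would use:

| parameter | default | meaning |
|---|---|---|
| `maf_min` | 0.02 | minimum minor allele frequency, computed over known allele copies only (missing calls never enter the denominator) |
| `depth_min`, `depth_max` | 10, 300 | closed depth window |
| `depth_mode` | `site_mean` | filter whole sites on mean known call depth; `genotype` instead masks individual out-of-window calls |
| `min_samples_per_site` | 40 | minimum genotyped samples per site (40-of-210 at the motivating study's scale) |
| `focal_min_carriers` | 3 | minimum focal samples carrying a non-reference allele (3-of-9 focal individuals at study scale) |
| `drop_ubiquitous` | on | drop sites whose non-reference alleles occur in every lineage |
| `require_focal_presence` | on | drop sites with no focal call |

Numerical conventions: both boundaries of the depth window are inclusive
(`--min-meanDP`/`--max-meanDP` semantics), the MAF comparison is `>=` with
a small epsilon guard against binary-representation artifacts, and for a
multiallelic site the MAF is the frequency of the second most frequent
allele. Sites with no depth information at all pass the depth stage with a
warning rather than being silently dropped, since absence of a DP field is
a property of the file, not evidence about the site. Two rules have
genuinely ambiguous readings and both readings are exposed:

* "Carried at least three times in the focal panel" is interpreted as
  *three distinct carrier individuals* (default); `carrier_mode = "copies"`
  counts allele copies instead, which differs exactly when carriers are
  homozygous.
* Depth can be judged per site (`site_mean`, the default, falling back to
  the site-level `INFO/DP` when no per-genotype depths exist) or per
  genotype (`genotype`); which one a given upstream pipeline used is often
  unrecorded, so both are provided.

Every stage is idempotent, and the cascade is exactly the composition of
the five stages — both properties are enforced by tests, which also pin
the boundary behaviour (MAF exactly at the floor is kept; depths exactly
10 and 300 are kept).

## Allele sharing

`build_allele_counts()` turns genotypes plus a popmap (sample → lineage,
lineage → clade, one focal lineage) into the long count table; hybrids
other than the focal lineage can be excluded at this point (`exclude =`)
so that sharing is assessed against clean diploid candidates. On top of it:

* `private_alleles()` — alleles observed in exactly one lineage;
* `shared_alleles()` — for each other lineage, alleles present in both it
  and the focal lineage;
* `exclusively_shared()` — present in exactly those two;
* `clade_sharing()` — presence in *any* member lineage counts; exclusive
  additionally requires absence outside the clade; unions of clades are
  merged clades.

Sharing is deliberately defined on **presence** (copy count > 0), not copy
counts: "present in exactly two lineages" is a presence criterion, and
presence is insensitive to the very different sample sizes per lineage that
real datasets have. `sharing_report()` reports percentages of the focal
lineage's *non-private* alleles — denominator `T - P` — half-up rounded to
2 decimals (commercial rounding, matching how such tables are typically
printed; R's own `round()` is banker's and would differ on exact halves).
A zero denominator yields undefined (`NA`) percentages, not an error.
`rank_parent_candidates()` orders lineages by shared count, breaking ties
by exclusive count and then label, so the result is deterministic.

The whole stack is verified two independent ways: a brute-force enumerator
(plain loops over every call) must agree exactly on a fully hand-enumerated
4-variant fixture and on 200 random matrices up to 20 variants x 12
samples, and the published percentage table of the motivating study is
reproduced to the printed 2 decimals from its printed integer counts alone.

## Shared heterozygosity and clonality

For samples $i, j$, let $H$ be the sites where both are genotyped and at
least one is heterozygous, and $M \subseteq H$ the sites where both are
heterozygous with identical unordered genotypes ($0/1 \equiv 1/0$, but
$0/1 \neq 0/2$). Then $\mathrm{SH}(i,j) = |M| / |H|$, undefined when
$H = \varnothing$. A pair is a clonemate pair when SH is defined and
**strictly** above the threshold (default 0.9); undefined pairs are never
flagged. The index is symmetric, equal to 1 for self-comparison with any
heterozygous site, and invariant to site order and to REF/ALT relabelling
— all property-tested.

The denominator is a real design choice. The default counts sites
heterozygous in *at least one* of the pair, which makes SH a proportion of
the pair's heterozygous sites and keeps it insensitive to shared
homozygosity; `denominator = "both"` (sites heterozygous in both) is
offered for sensitivity analysis, since published descriptions of the index
do not always pin this down. The default is the stricter of the two for
clone detection: any site het in one sample but not the other counts
against the pair.

`pairwise_sh()` scores intra-lineage pairs by default — clonality is an
intra-lineage question, and that is also what the conventional threshold
was calibrated on; `scope = "all_pairs"` exists for exploration. Lineages
with fewer than two samples simply contribute no pairs.

## The synthetic-data model

`simulate_dataset()` generates datasets with the structure the inference
assumes, plus ground truth for every claim a test makes:

* **Hierarchical Balding–Nichols drift.** Per locus, an ancestral frequency
  $p \sim U(0.05, 0.95)$; each clade draws
  $p_c \sim \mathrm{Beta}\!\big(p\tfrac{1-F_c}{F_c}, (1-p)\tfrac{1-F_c}{F_c}\big)$
  with $F_c = 0.15$; each lineage draws around its clade frequency the same
  way with $F_l = 0.05$. Diploid genotypes are $\mathrm{Bin}(2, p_l)$.
  This was chosen over coalescent simulation for speed and closed-form
  expectations; it is a modelling stand-in, not a claim about the real
  system. The default layout is three clades of 3, 4 and 2 diploid
  lineages with 8 samples each.
* **Allotetraploid with disomic inheritance.** Each of the 9 focal samples
  draws 2 allele copies from parent A's lineage frequency and 2 from parent
  B's — a fixed 2+2 subgenome contribution with no tetrasomic mixing — and
  is exported as a pseudo-diploid call: heterozygous exactly when both
  states occur among the four copies. This mimics diploid genotype calling
  of GBS reads from a tetraploid; the true dosage is retained in the truth
  record.
* **Clones.** Ramets copy a progenitor's genotypes with an independent
  per-site error (a genotype resampled from the generating model), so
  error 0 gives SH exactly 1 against the progenitor.
* **Noise.** Uniform missingness (default rate 0.2 — GBS datasets routinely
  lose a fifth or more of calls per site), negative-binomial per-genotype
  depths (mean 50, dispersion 5, matching a mid-coverage GBS run), and
  optional indel records. `inject_artifacts()` applies the same artifact
  layer to any genotype table and returns exactly what it injected, so
  filter tests can check *exact* recovery rather than statistical
  agreement.

All randomness flows from the single `seed`; replicate $k$ of a multi-run
experiment uses `seed + k`. Identical configurations produce byte-identical
VCFs.

What the simulator does **not** emulate: linkage between loci (all loci are
independent), selection, allele-frequency spectra of real ascertained SNP
panels, locus dropout that is correlated with divergence (allele dropout in
GBS is systematically worse in distant taxa), sequencing error in
homozygotes, or chloroplast haplotypes (so maternal-parent assignment is
out of scope). Passing recovery tests therefore show the statistics behave
correctly under the assumed population model — not that the model captures
every property of a real GBS matrix.

## What recovery tests can and cannot show

With the default divergence settings, clade-level recovery is strong: the
two clades containing the true parents take the two highest clade
percentages essentially always, and injected clonemates (error ≤ 0.01)
separate cleanly from sexual pairs (which concentrate around SH 0.2–0.6).
Lineage-level recovery is a different matter. At $F_l = 0.05$, sibling
lineages within a clade are so similar that presence-based sharing
saturates: nearly every focal allele is present in nearly every lineage,
the expected parent-versus-sibling excess is of the same order as its
binomial sampling noise, and the top-two ranking frequently swaps a parent
for one of its siblings. This is not an implementation artifact — a direct
Monte Carlo of the model expectations puts the standardised
parent-vs-sibling gap near $z \approx 1.2$ at these settings — and it has a
faithful biological reading: allele sharing identifies parental *clades*
robustly, but resolves the individual parent only when candidate lineages
are well diverged relative to sampling noise. Real studies of
allopolyploids with extinct parents reach exactly clade-level conclusions.
The acceptance checks report both rates; the lineage-level one should be
read with this in mind.

## Problem sizes and runtimes

The test suite validates against brute force at up to 20 variants x 12
samples (200 random matrices), and runs recovery experiments at 10
replicates of 5,000 loci x 81 samples for parent/clade ranking, 2,000 loci
for clone detection, and 400–1,000 loci for artifact-filter checks — sizes
chosen so the full suite completes in a couple of minutes on one CPU while
keeping the per-replicate sampling noise representative of a GBS study.
The acceptance script uses the same sizes.

## Known limitations

* Maternal-versus-paternal assignment needs organellar data and is out of
  scope; the report ranks nuclear sharing only.
* No multilocus-genotype clustering: clonality is assessed pairwise, not by
  assigning samples to genets (transitively inconsistent triples are
  possible near the threshold).
* The percentage denominator convention (non-private alleles) matches the
  published tables this package mirrors; other studies sometimes divide by
  the focal total instead. Use `tidy()` on a report to recompute under any
  convention.
* `read_vcf()` targets the plain, uncompressed VCFs that GBS pipelines
  emit; bgzipped/indexed VCF and BCF are not handled.
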