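Package: polyshare
Title: Allele Sharing, Clonality and Parentage Inference for
    Allopolyploids from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to infer the parental origin and reproductive mode of
    allopolyploid plant lineages from genotyping-by-sequencing (GBS) SNP
    matrices.  Provides a vcftools-style variant filter cascade (indel
    removal, minor allele frequency, depth window, site presence, and
    focal-informativeness rules), per-lineage allele-count tables with
    private, shared, and exclusively shared allele accounting aggregated
    to clades, a pairwise shared-heterozygosity (SH) index with
    clonemate classification, and a hierarchical Balding-Nichols
    simulator of diverged diploid lineages with an allotetraploid hybrid
    under disomic inheritance for validation of every stage.  All
    user-facing functions take and return tidy tibbles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
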