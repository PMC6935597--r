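Package: popflow
Title: Lineage Structure, Cytonuclear Discordance and Pool-Seq
    Differentiation for Riparian Cottonwood Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for range-wide population-genomic surveys of
    riparian trees genotyped on small SNP arrays and pool-sequenced by
    lineage.  Covers sample quality control (hybrid exclusion, clone
    removal, missingness filtering), diversity and differentiation
    indices (Ho, Hs, Ht, Fis, Nei Gst and Weir-Cockerham theta),
    hierarchical AMOVA with permutation tests, admixture Q-value
    threshold classification, chloroplast haplotype construction and
    directional chloroplast-capture detection, pool-sequencing variant
    filtering with a detection limit, endemic-SNP classification,
    per-SNP and windowed Fst genome scans, and two-dimensional joint
    allele-frequency spectra scored against divergence-with-gene-flow
    models by forward Wright-Fisher simulation.  A synthetic-data
    generator with a planted truth ledger makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
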