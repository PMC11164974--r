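Package: msytools
Title: Male-Specific Y Chromosome Discovery, Haplotype Phylogeny, Dating and Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for paternal-lineage population genomics from short-read
    whole-genome sequencing of non-model mammals. Discovers male-specific Y (MSY)
    sequence from sex-stratified read depth, classifies 50-bp windows into
    single-copy Y, multi-copy Y and non-Y states with a probabilistic coverage
    model, applies a haploid SNP filter cascade with per-depth-group rules,
    builds maximum-parsimony haplotype trees by perfect-phylogeny construction,
    names haplogroups hierarchically, dates nodes with a calibration-point
    strict molecular clock, and estimates Watterson's theta per sample group.
    A synthetic-data module generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vcfR,
    withr
Config/testthat/edition: 3
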