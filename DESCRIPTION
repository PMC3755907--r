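Package: mapipe
Title: Mutation-Accumulation Sequencing Analysis for Mismatch Repair
    Deficient Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Analysis pipeline for whole-genome mutation accumulation (MA)
    experiments in hypermutator (mismatch repair deficient) yeast strains.
    Provides a perfect tandem-repeat census of a reference genome
    (homopolymeric runs and di-/tri-/tetranucleotide microsatellites),
    classification of fixed mutation calls into a strand-collapsed
    substitution and slippage-indel spectrum, per-base-pair and
    repeat-length-stratified mutation-rate estimation with exponential and
    linear regime fits, insertion/deletion bias and repeat-proximity
    statistics, Luria-Delbruck fluctuation-assay estimators (P0 and
    Ma-Sandri-Sarkar maximum likelihood), and a fully deterministic
    synthetic-data generator (genomes, MA lineages, fluctuation cultures)
    so the whole pipeline can be exercised and calibrated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
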