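Package: radmarkr
Title: De Novo SNP and Microsatellite Marker Discovery from RAD-Seq and
    Shotgun Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable implementation of a dual-platform de novo
    marker-discovery workflow for low-diversity diploid species. Covers
    restriction-digest prediction and RAD-tag extraction, demultiplexing,
    unitag clustering and local de Bruijn assembly of RAD paired-end reads,
    read mapping and allele-frequency-threshold genotype calling,
    quality-gated SNP and indel calling for long-read shotgun data,
    genotyping-assay design filters, paralog flagging via fixed
    heterozygosity, perfect-microsatellite detection with potentially
    amplifiable locus (PAL) classification, and replicate-based genotyping
    quality control (allelic dropout and false allele rates). A fully
    seeded synthetic-data generator emulates the study design (diploid
    genome, EagI restriction sites, barcoded asymmetric paired-end RAD
    reads, long shotgun reads, replicate PCR genotypes) so every stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
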