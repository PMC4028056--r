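Package: vcgtools
Title: Virtual Consensus Genomes from Multi-Sample Low-Coverage Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds population-level "virtual" consensus reference genomes
    from multi-sample low-coverage pileup data. Parses samtools mpileup
    text into position-based records, filters per-sample units by Shannon
    comentropy with arity-specific thresholds, extracts candidate dynamic
    positions, computes equal-sample-weight population allele statistics,
    classifies dynamic positions (major-allele differences, high-probability
    indels, common minor alleles, rare variations), derives the
    major-allele-and-indel-against-reference (MAIR) edit set, and applies
    it to the linear reference with an indel-aware coordinate liftover map.
    Includes a seeded simulator of diploid populations sequenced at
    Poisson low coverage, summary reports, population comparisons, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14),
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
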