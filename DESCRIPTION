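Package: radmut
Title: Discovery of Radiation-Induced Mutations in Mutagenized Plant Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies mutations induced by gamma or X-ray irradiation in
    whole-genome sequenced mutant plant lines. Implements allele-ratio
    zygosity recalibration of heterozygous genotype calls, a four-step
    natural-variation filtering cascade over replicated multi-sample variant
    calls (control subtraction, cross-line sharing, replicate concordance,
    database subtraction), structural-variant consolidation across callers
    with coordinate-tolerance merging and read-support thresholds, read-depth
    bin scanning for large deletions and duplications, codon-level variant
    effect classification against reference gene models, and mutation
    spectrum and density reporting. A synthetic-data generator emulates a
    replicated mutagenized population with machine-readable truth tables so
    every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
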