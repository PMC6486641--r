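Package: haplomet
Title: Haplotype-Resolved CpG Methylation from Nanopore Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct haplotyped methylomes from long-read nanopore
    sequencing of F1 hybrid samples. Assigns each read to a parental haplotype by
    combining basecall-level and signal-level evidence at strain SNPs, resolves
    grand-parental recombination segments with a recursive-partition fit of
    windowed haplotype proportions, converts per-read methylation log-likelihoods
    into probabilities over chained CpG call groups, detects allele-specific
    differentially methylated regions with a beta-binomial Wald test on an
    arcsine-transformed count matrix, compares calls against bisulfite data, and
    smooths per-read methylation tracks for visualization. A synthetic-data
    generator emulates every input format with known truth so the whole pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rpart,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
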