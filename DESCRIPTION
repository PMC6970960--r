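Package: mhctyper
Title: Amplicon-Based MHC Genotyping and Haplotyping for Atlantic Salmon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an Illumina amplicon-sequencing workflow for typing the
    classical major histocompatibility complex (MHC) genes of Atlantic salmon
    (class I UBA and class II DAA/DAB): per-animal paired-end FASTQ input,
    quality trimming, exact-match primer demultiplexing, overlap-based read
    pair merging, dereplication of merged amplicons, classification of
    candidate alleles against a reference allele library with
    colon-delimited IPD-MHC-style nomenclature proposals, exclusion of
    jumping-PCR chimeras, per-animal genotype calls with zygosity, and
    parsimony phasing of DAA-DAB haplotypes across animals. A seeded
    synthetic-read generator with a truth table makes every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
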