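Package: hybridly
Title: Diagnosing F1 Hybrid Origin from Genomic SNP, Ribosomal and
    Organellar Evidence
Version: 0.1.0
Authors@R:
    person("Ada", "Quick", email = "ada.quick@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether a putative hybrid plant is a first
    generation (F1) cross of two candidate parent species using whole
    genome shotgun reads. Includes a truth-known synthetic data
    generator, an ungapped seed-and-extend read mapper with a
    threshold-based diploid genotype caller, per-contig SNP density
    statistics, a Venn-style partition of the hybrid's alleles among
    candidate parents with an exact binomial test of the F1
    half-sharing expectation, chloroplast pairwise distances for
    maternal parent assignment, intragenomic nuclear ribosomal spacer
    (ITS) allele characterization, an alignment- and assembly-free
    k-mer phylogeny, and an integrated machine-readable parentage
    verdict.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    Biostrings,
    S4Vectors
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
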