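Package: cosnpr
Title: Coincident SNP Enrichment Analysis for Orthologous Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying coincident single nucleotide polymorphisms
    (coSNPs), orthologous coding positions polymorphic in each of two compared
    species, and for testing the forces that shape their distribution. Builds
    orthologous coding-site tables from FASTA/VCF/TSV inputs, classifies codon
    degeneracy and CpG context, computes observed-to-expected coSNP ratios with
    chi-square independence tests, dimorphic allele-pattern tables, site
    frequency spectra, Tajima's D window classes, constraint-binned trend
    tests, nearest-neighbour functional comparisons, and SNP discovery-curve
    extrapolation. Includes a two-population Wright-Fisher forward simulator
    under purifying selection (compiled) and a synthetic-data generator that
    emulates per-site mutation-rate heterogeneity, constrained-site masks,
    shared ancestral polymorphism, and correlated annotation scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    vcfR,
    ape,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
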