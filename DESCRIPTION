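Package: kinmatch
Title: Kinship Classification from Pairwise Mismatch Rates in Low-Coverage Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Infers biological relatedness between pairs of individuals from
    pseudo-haploid or diploid genotype calls, the standard input for
    low-coverage ancient DNA studies. Estimates the pairwise mismatch rate
    (P0) genome-wide or in windows, normalizes it by the expected mismatch of
    an unrelated pair, and classifies pairs as identical/twins, first-,
    second-, or third-degree relatives with block-jackknife standard errors
    and data-amount gating. First-degree pairs are further resolved into
    parent-offspring versus full siblings from the proportion of 20-Mb
    windows sharing zero or two chromosomes. Includes a pedigree simulator
    with recombination and a Poisson site-coverage model that emits PLINK
    bed/bim/fam files plus a relationship truth table for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
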