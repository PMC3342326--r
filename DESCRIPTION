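Package: foundertracker
Title: Genome-Wide Detection of Founder Mutations from Tumor SNP Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps founder mutations in cancer from dense SNP-array data.
    Tumor haplotypes are read directly off B-allele-frequency profiles inside
    recurrent regions of loss of heterozygosity (LOH), pairwise identity by
    descent (IBD) between the exposed haplotypes is detected with a
    seed-and-extend matcher, and a per-SNP IBD score summing the
    frequency-weighted log-probabilities of all shared segments is tested
    against a Gumbel null distribution calibrated by resampling subsets of a
    reference haplotype panel. Includes a cluster-plus-Fisher benchmark
    scan, a mosaic haplotype-panel simulator, and a power/false-discovery
    evaluation harness for planted conserved haplotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
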