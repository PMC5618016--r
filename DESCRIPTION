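Package: gvmix
Title: Genome-Group Mixture Deconvolution for Pooled Virus Isolate Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies and quantifies the genome-group composition of mixed
    granulovirus isolates from pooled short-read sequencing. Builds a
    lineage-specific SNP map from a multi-genome alignment of reference
    isolates, maps quality-filtered paired-end reads against the alignment
    consensus, measures per-site allele frequencies, and estimates mixture
    proportions by data-size-weighted medians over combined genome groups,
    with trace-group correction and Tukey-HSD group comparisons. Includes a
    paired-end read simulator (substitution errors, host-DNA contamination,
    circular genomes) that provides planted ground truth for every stage,
    and Abbott-corrected summaries of insect bioassay mortality tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    Rcpp,
    Rsamtools,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
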