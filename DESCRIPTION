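Package: palmethyl
Title: Differential Cytosine Methylation Analysis for Paired-Condition
    Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Paired-condition analysis of whole-genome bisulfite sequencing
    (WGBS) methylomes at single-cytosine resolution in the CG, CHG and CHH
    sequence contexts. Calls differentially methylated sites (Fisher exact
    test with Benjamini-Hochberg correction and a +/-33 percentage-point
    strong/weak classification), 50-bp differentially methylated regions with
    per-context net methylation-change summaries, and gene-level differential
    methylation stratified by promoter, exon and intron features. Builds
    metagene methylation landscapes around gene bodies and promoters for
    expression-level groups and pseudogenes, correlates gene methylation with
    RNA-seq expression (FPKM) using tenth-of-minimum pseudocounts, estimates
    bisulfite conversion rates from an unmethylated plastid genome, and ships
    a seeded synthetic-data generator that emulates Bismark cytosine reports
    and expression tables with planted, machine-readable truth for
    benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
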