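Package: smrpipe
Title: Summary-Data Mendelian Randomization for Multi-Omics Integration
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates mQTL, eQTL and GWAS summary statistics by summary-data
    Mendelian randomization (SMR). Implements the single-instrument SMR test,
    the HEIDI heterogeneity test that separates pleiotropy from linkage, a
    multi-SNP SMR test based on a saddlepoint-approximated quadratic-form
    p-value, the three-step methylome-to-transcriptome-to-trait pipeline
    (M2T, T2M and omics-to-trait scans with Bonferroni and HEIDI filtering,
    triplet combination, nearest-gene and direction-concordance summaries),
    a chromatin-state enrichment test with variance-matched resampling, and a
    coupled genotype/DNAm/expression/trait simulator that emits every summary
    format the pipeline consumes, so all statistical claims are testable
    without external data. Reads GCTA-COJO .ma summary files, flat cis-QTL
    tables and PLINK bed/bim/fam reference panels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils,
    tools,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
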