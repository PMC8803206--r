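Package: apmeth
Title: Alternative Promoter Usage and DNA Methylation Integration for
    Paired Tumor/Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies promoter activity from RNA-seq splice-junction
    tables and a gene-model annotation, calls differentially regulated
    promoters (DRPs) and alternative promoters (APs) between paired tumor
    and normal samples, links promoters to representative CpG methylation
    probes to identify methylation-regulated alternative promoters
    (mrAPs), and evaluates their clinical value with an L1-penalised
    logistic diagnostic model and maximally selected survival cutpoints.
    Includes a synthetic-data generator producing paired tumor/normal
    junction counts, methylation beta values, and survival data with
    planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    glmnet,
    GenomicRanges,
    IRanges,
    jsonlite,
    mgcv,
    rtracklayer,
    S4Vectors,
    stats,
    survival,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
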