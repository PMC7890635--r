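Package: xciscape
Title: Cross-Species X-Chromosome Inactivation Status Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls X-chromosome inactivation (XCI) status -- escape,
    variable escape or subject -- for X-linked genes from two independent
    data types: allelic (Xi/Xa) expression read counts in samples with
    skewed Xi choice, analysed with an exact binomial model against a 0.1
    Xi/Xa ratio threshold; and promoter CpG-island DNA methylation from
    WGBS, RRBS or 450k-array data, classified with 10/15/60% methylation
    thresholds and a male-hypermethylation filter.  Per-dataset calls are
    merged across species by gene symbol to classify conservation and
    discordance of XCI status, detect escape domains and their coincidence
    with TAD boundaries, test enrichment of repeat classes, predicted CTCF
    binding and ATAC-seq accessibility around genes by status, and cluster
    species by their call profiles with Gower distance and complete
    linkage.  A synthetic multi-species cohort generator with known ground
    truth makes the full pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    IRanges,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    withr
Config/testthat/edition: 3
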