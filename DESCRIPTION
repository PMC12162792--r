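Package: promethex
Title: Promoter Methylation and Transcription Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking whole-genome bisulfite sequencing
    methylation to RNA-seq transcription around gene promoters. Provides
    per-CpG differential methylation testing by binomial logistic
    regression with overdispersion correction, coverage filtering and
    median-based coverage normalization, a re-implementation of
    TMM-normalized negative-binomial differential expression with
    dispersion shrinkage, strand-aware promoter window tiling at multiple
    resolutions with per-window differential methylation calls,
    TSS-anchored methylation metaplots, static and dynamic
    methylation-expression association summaries (overlap accounting and
    per-window regressions), and a joint beta-binomial/negative-binomial
    simulator that generates WGBS and RNA-seq data with configurable
    methylation-expression coupling for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
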