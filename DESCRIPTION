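Package: refstab
Title: Reference Gene Selection and Expression Stability Analysis for
    RT-qPCR Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects and validates candidate reference (housekeeping) genes
    for RT-qPCR normalization, with an emphasis on platelet transcriptomes
    in pan-cancer studies. Provides an RNA-seq shortlisting cascade
    (sample-depth and zero-count filters, log2 counts-per-million
    transformation, fold-change / top-decile / coefficient-of-variation
    criteria, and intersection with a curated known-reference list), four
    cycle-threshold expression-stability algorithms (comparative delta-Ct,
    geNorm, NormFinder, BestKeeper), geometric-mean rank aggregation into a
    comprehensive ranking, relative-expression validation via the
    delta-delta-Ct method, and seeded synthetic-data generators for count
    matrices and Ct panels with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
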