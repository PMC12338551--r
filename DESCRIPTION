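Package: hitdecon
Title: Target and Pathway Deconvolution of Phenotypic Screening Hits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links hit compounds from a phenotypic high-throughput screen to
    protein targets and biological pathways. Screening-library structures are
    standardized (salt stripping, charge neutralization, InChIKey generation),
    mapped to per-source compound identifiers, and joined to offline dumps of
    curated and bioactivity compound-target annotation sources with each
    source's potency, organism and assay filters applied. Per-target
    overrepresentation among hits is tested against the empirical screening
    background with Fisher's exact test and Benjamini-Hochberg adjustment,
    each (hit, enriched target) pair is classified as inhibitor, activator,
    mixed, inconclusive or unknown from its activity evidence, and enriched
    target sets are carried into gene-set pathway overrepresentation. A
    synthetic-screen generator with planted ground truth makes the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    xml2,
    jsonlite,
    ggplot2,
    generics,
    ChemmineOB,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
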