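Package: bh3map
Title: Mapping BCL-2 Family Gene Dependencies from BH3-Mimetic Viability Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for combinatorial BH3-mimetic viability
    screens across cancer cell line panels. Converts raw luminescence
    signals into 0-99 viability-loss ("dependency") scores, computes
    Bliss synergy for BCL-XL + MCL-1 co-inhibition, compares tissue
    against mutation status as dependency predictors by linear-model
    goodness of fit, finds gene-expression thresholds that segregate
    sensitive from resistant lines by a sliding-scale t-test search,
    scores epithelial and mesenchymal marker-sum signatures, performs
    tissue-average outlier analysis, and scores negative-selection
    pooled CRISPR screens with a best-3-sgRNA depletion metric. A
    seeded synthetic-data generator with planted effects makes every
    stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
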