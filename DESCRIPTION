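Package: ctcollab
Title: Collaboration Network Recommendation for Clinical Trial Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cumulative weighted co-collaboration networks from
    clinical-trial registry exports, fuses geographical and intervention
    attributes into node features, trains graph neural network link
    predictors (two-layer GCN or GraphSAGE-mean encoders with a dot-product
    decoder), and produces ranked collaboration-partner recommendations
    together with AUC, F1 and Accuracy@K evaluation under temporal or
    random edge splits. Includes a planted-partition synthetic registry
    generator so the full pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    digest,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
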