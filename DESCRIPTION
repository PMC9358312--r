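Package: apegest
Title: Social Predictors of Gestural Complexity in Apes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the complexity and effectiveness of ape
    gestural communication from focal-animal observation data. Provides a
    validated data model for coded gesture events and proximity scans,
    temporal-window segmentation of gestures into sequences, proximity-based
    social network indices (eigenvector centrality, dyadic bond scores,
    maternal kinship), individual- and dyad-level complexity metrics
    (repertoire size, attention accounting, contextual flexibility, sequence
    use, response elicitation), Cohen's kappa for coder reliability, and a
    suite of binomial and beta regressions linking complexity to sociality,
    with model comparison and species contrasts. A seeded synthetic-data
    generator emulates the focal/scan sampling design with configurable
    planted effect sizes so the whole pipeline can be exercised and
    parameter recovery verified without observational data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    glmmTMB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
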