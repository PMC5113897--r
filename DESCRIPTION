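Package: garf
Title: Genetic-Algorithm/Random-Forest Reduction of Gene Expression Panels
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reduces large gene-expression classification signatures to small
    fixed-size gene panels that reproduce a reference classification across
    multiple cohorts. A genetic algorithm samples candidate panels from a
    shrinking gene pool, scores each panel by the classification concordance
    of a random forest trained on it, and retains the genes of the top models
    under a dynamic survivor rule until mean fitness stops improving. Includes
    the random-model accuracy curve procedure for choosing the panel size,
    cross-cohort preprocessing (quantile normalization, batch adjustment,
    rank normalization), a final reduced-panel classifier, and a seeded
    multi-cohort simulator with planted class-informative genes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    limma,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
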