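Package: descope
Title: Contextual Comparison of Differential-Expression Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for exploring many differential-expression (DE)
    result tables at once. Experiments are embedded in a two-dimensional
    similarity map by principal component analysis of the experiments-by-genes
    p-value matrix, computed with a seeded randomized singular value
    decomposition and recomputable on any gene subset. A cumulative
    filter/brush/link selection model, hexagonal-binning plot models with the
    eight standard axis transforms, Gene Ontology term coverage scoring, and a
    synthetic-data generator with planted similarity clusters, inverted
    comparisons and enriched terms make the whole workflow scriptable and
    testable without any network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
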