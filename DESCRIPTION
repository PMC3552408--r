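Package: adaptdiff
Title: Measuring and Predicting Local Adaptation in Fragmented Plant
    Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for quantifying adaptive differentiation among
    fragmented plant populations and predicting where local adaptation
    occurs. Estimates pairwise quantitative genetic differentiation (Q_ST)
    from half-sib family trait data by method-of-moments variance
    components, pairwise neutral differentiation (Weir-Cockerham theta)
    from codominant multi-allelic genotypes, and environmental distance
    from rotated principal-component factor scores; relates the resulting
    distance matrices by Mantel permutation tests; and analyses paired
    local/foreign transplant experiments via fitness differentials,
    origin-by-pair tests on family means, and stepwise AIC regressions of
    local-adaptation differentials on candidate predictors. Includes a
    synthetic-data generator with known ground truth so every stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
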