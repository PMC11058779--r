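Package: streamhealth
Title: Ecological Health Assessment of Wadable Streams from Fish
    Communities and Water Chemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for guild-based bioassessment of wadable rivers and
    streams. Builds fish ecological entities (FEs) by exact matching of
    trophic, habitat, and tolerance guild labels; computes the fish-based
    multi-metric index of biotic integrity (mIBI-F) and the multi-metric
    water pollution index (mWPI) with configurable 5/3/1 scoring criteria
    and health-class bands; clusters sites by log-transformed water
    chemistry with Ward.D2 agglomeration; ordinates communities by
    nonmetric multidimensional scaling (Kruskal stress-1 with
    pool-adjacent-violators isotonic regression) on Bray-Curtis
    dissimilarities; and links ordination site scores to chemical health
    indicators and riparian covariates through correlation and simple
    linear regression. A synthetic-data generator plants a pollution
    gradient with guild-linked abundance responses so the whole pipeline
    can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
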