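Package: percsim
Title: Perceptual Color and Texture Similarity Scoring of Skin Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how visible a target skin patch (a basal cell
    carcinoma site or post-treatment scar) is against perilesional healthy
    skin. Computes mean-color distances (Euclidean, Bray-Curtis, DeltaE,
    CIE94) in RGB, YIQ and CIELAB, and deep-embedding texture similarities
    (layer-wise and fully-connected cosine similarity over a convolutional
    backbone), aggregates them over patch triplets, maps the continuous
    similarities to a 4-level ordinal visibility scale with
    proportional-odds regression, and validates the mapping with repeated
    class-balanced splits (MSE, absolute and adjacent accuracy), k-means
    cluster summaries, and inter-rater agreement statistics (Cronbach's
    alpha, quadratic Cohen's kappa, Gwet's AC2, rank-sum group
    comparisons). Includes a seeded synthetic-data generator producing
    patch triplets with controlled color and texture deviations and
    simulated expert rater panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
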