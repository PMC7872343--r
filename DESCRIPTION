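Package: mvbmd
Title: Multivariate Classification of Osteoporosis and Osteopenia from
    DXA T-Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a multivariate alternative to the WHO/ISCD
    lowest-T-score diagnosis of osteoporosis and osteopenia from
    dual-energy X-ray absorptiometry (DXA). The three bone mineral
    density T-scores (L1-L4 lumbar spine, femoral neck, total hip) are
    classified jointly with Mahalanobis confidence ellipsoids whose
    boundary radii are constrained to the univariate -2.5 and -1.0
    thresholds. Provides the supporting multivariate-t / multivariate
    normal distribution theory for T-score vectors (joint, marginal and
    conditional densities, analytic category coverage), seeded
    simulation of equicorrelated and real-cohort-like trivariate normal
    T-score cohorts, paired comparison of the two diagnostic rules via
    McNemar's test, FRAX risk group comparison, cohort CSV input and
    output, ellipsoid mesh export, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
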