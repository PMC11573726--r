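Package: isoelev
Title: Stable-Isotope Inference of Diet and Elevational Origin in Andean Mice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for liver stable-isotope trophic ecology along elevational
    gradients: lipid normalization of bulk delta-13C from the tissue C:N
    ratio, construction of plant isotopic baselines by elevational bin
    (including two-source C3 versus C4/CAM splits of bimodal bins), Bayesian
    trophic-position estimation at the population and individual level via
    MCMC, permutation-based multivariate analysis of variance (PERMANOVA)
    with pairwise post hoc tests, and canonical analysis of principal
    coordinates (CAP) with leave-one-out cross-validation and assignment of
    new individuals to elevational zones. Includes seeded generators for
    synthetic consumer and plant datasets with known trophic position, and a
    pipeline runner producing report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS
Config/testthat/edition: 3
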