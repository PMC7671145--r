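Package: phylosize
Title: Phylogenetically Informed Allometry and Bayesian Body-Size Prediction
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates allometric scaling of body-size metrics (body mass,
    snout-vent length, total length) on head width across a phylogeny, using
    phylogenetic generalized least squares with Brownian-motion covariance,
    phylogenetic signal statistics (Pagel's lambda by maximum likelihood,
    Blomberg's K with permutation tests), and Bayesian phylogenetic
    prediction of size traits for query tips (e.g. fossils) grafted onto the
    tree with near-zero branch lengths.  Includes specimen-level polytomy
    expansion, confidence and prediction bands from the phylogenetic
    variance-covariance matrix, studentized-residual outlier diagnostics,
    isometry tests, a seeded synthetic-data generator with known ground
    truth, and an end-to-end pipeline with CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
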