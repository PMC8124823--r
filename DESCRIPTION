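Package: jnposture
Title: Joint-Node Plots for Postural Control Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, rendering and classification tools for image-based
    assessment of standing postural control. Generates synthetic 15-joint
    skeleton trajectories for quiet stance (group-dependent sway plus
    segment-specific tremor phenotypes), rasterizes each 40-second recording
    into a deterministic joint-node plot (JNP), extracts image features with
    interchangeable backends (per-joint colour moments or a small trainable
    convolutional network), evaluates support vector machine, logistic
    regression and naive Bayes classifiers over a reproducible model grid,
    and reports six confusion-matrix indices ranked by Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    glmnet,
    graphics,
    jsonlite,
    png,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
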