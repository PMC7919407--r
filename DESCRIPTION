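Package: ssrox
Title: Simulation and Merging Statistics for Serial Synchrotron Rotation
    Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate data-collection strategies for room-temperature
    serial synchrotron rotation crystallography (SS-ROX). Provides a synthetic
    experiment generator (Wilson-distributed intensities, Poisson multi-crystal
    hits, per-image scales and partialities, dose-dependent B-factor damage and
    unit-cell drift), Monte Carlo merging with per-image linear scaling and
    Lorentz correction, half-set quality statistics (CC1/2, Rsplit) in
    resolution shells, a variable-plateau tanh CC1/2 resolution estimator, a
    logarithmic resolution-versus-photons scaling law with a Wilson-plot
    interpretation, and dose/photon/hit-rate bookkeeping. Results are tibbles
    designed for pipe-based analysis, with tidy()/glance() methods and ggplot2
    autoplot() graphics.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
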