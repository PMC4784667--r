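Package: anomsig
Title: Scaling, Merging and Anomalous-Signal Estimation for SAD Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-wavelength anomalous diffraction (SAD)
    experiments: local scaling and merging of unmerged reflection data from
    one or more crystals with explicit modelling of inter-data-set variance,
    data-quality metrics for anomalous differences (half-data-set anomalous
    correlation and the derived CC* estimate, anomalous difference Patterson
    skew, normalized error from rescaled uncertainties), Bayesian estimation
    of the useful anomalous correlation, and planning calculations that
    predict the anomalous signal, the probability of substructure solution
    and the expected phasing quality before and after data collection. A
    seeded synthetic-data generator produces ground-truth crystals with known
    anomalous substructures for validation and estimator training.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
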