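Package: isebayes
Title: Bayesian Calibration and Quantification for Ion-Selective Electrodes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonlinear Bayesian calibration of ion-selective electrodes (ISEs)
    using the Nikolsky-Eisenman response model, for single electrodes and
    multi-electrode arrays. Supports concentration estimation by direct
    potentiometry and by standard addition (robust to baseline drift),
    detection-limit estimation (classical IUPAC intersection limit, the
    traditional limit of quantification, and a detection-theoretic Bayesian
    limit), and method-comparison statistics (Pearson correlation, extraction
    recovery, log-scale residuals, credible-interval width comparisons).
    Includes a synthetic-data generator emulating calibration series, drifting
    sample emf readings, standard-addition series and paired method-comparison
    tables for nitrate and ammonium monitoring in soil extracts and water.
    Posterior sampling is performed with JAGS via rjags.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
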