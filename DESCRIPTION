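Package: fishbiom
Title: Length-Based Biometric Indices and Stock Assessment for Riverine Fish
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a length-based assessment workflow for data-limited
    riverine fish stocks: length-frequency distributions and descriptive
    statistics, length-weight and length-length regressions with tests
    against isometry, empirical estimators of von Bertalanffy growth
    parameters (asymptotic length and weight, growth performance index,
    longevity, age at zero length), Froese's form factor, condition factors
    (allometric, Fulton's, relative) and relative weight with their
    associated rank tests, length- and age-at-maturity and optimum catchable
    length reference points with Froese's catch sustainability indicators,
    and mortality and exploitation rates from a length-converted catch
    curve. A steady-state population simulator with logistic gear
    selectivity supports end-to-end testing and parameter-recovery
    experiments without field data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
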