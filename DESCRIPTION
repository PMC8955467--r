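Package: aerodepo
Title: Dry Powder Inhaler Aerosol Spectrometry and Lung Deposition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing of log-binned optical aerosol spectrometer counts
    (differential number distributions, mean particle diameter, number
    concentrations, background correction), characterization of dry powder
    inhaler and breathing-system airflow resistance from flow and pressure
    traces, computation of inhaled-versus-exhaled lung deposition and
    exhaled particle fractions from paired spectra, and nonparametric
    (Kruskal-Wallis) comparison of inhaled and exhaled metrics. Includes a
    calibrated synthetic generator that emulates a mechanical breathing
    simulator with an upper-airway impaction filter and a U-shaped lung
    retention curve, so the full pipeline runs and is tested without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    pkgload
Config/testthat/edition: 3
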