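Package: aquastore
Title: Aquaphotomics Monitoring of Fruit in Cold Storage from NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for monitoring stored fruit with near-infrared
    spectroscopy of the water first overtone region: standard normal
    variate preprocessing and day-to-day difference spectra, SIMCA
    storage-day classification with interclass distances and
    discriminating power, NIPALS PLS1 regression of spectra on storage
    time with segment-exclusion cross-validation, aggregation of
    influential wavelengths onto the water matrix coordinates (WAMACS)
    catalogue, classical aquagram water spectral patterns, weight-loss
    statistics, and a synthetic generator emulating a two-fridge
    strawberry storage experiment.
License: MIT
Encoding: UTF-8
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
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
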