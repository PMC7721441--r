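Package: filocal
Title: Astrocyte Microdomain Calcium Transients and Tracheal Filopodia
    Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of astrocyte microdomain Ca2+
    transients in two-channel time-lapse fluorescence movies, tracking and
    motility classification of tracheal filopodia, and the spatiotemporal
    coupling statistics that relate the two: tip-in-domain overlap, event
    peak to retraction-onset latencies, onset-versus-peak regression, and a
    bystander spatial null. Includes a synthetic movie generator with known
    ground truth so every analysis stage can be validated by parameter
    recovery, plus a reproducible simulate-detect-track-couple-report
    pipeline with epoch (pre/post bath application) statistics.
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
    igraph,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
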