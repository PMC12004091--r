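Package: ppafire
Title: Persistent Positive Anomalies in Geopotential Height and Wildfire Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and tracks persistent positive anomaly (PPA) events -
    blocking-like, long-lived ridges in gridded 500 hPa geopotential height -
    and quantifies their association with surface fire weather and wildfire
    burned area. Provides daily climatologies and anomalies with a seasonally
    varying magnitude threshold, spatiotemporal event clustering and tracking,
    the Canadian Fire Weather Index System (FFMC, DMC, DC, ISI, BUI, FWI)
    with daily moisture carry-over, vapour pressure deficit and the
    hot-dry-windy index, Haldane-corrected odds ratios from per-cell-month
    contingency tables, burned-area attribution, lead-lag composites around
    maximum event strength, and per-cell regression t-statistics. A fully
    seeded synthetic-data generator with known ground truth (injected events,
    coupled surface weather, fires with a configurable exposure odds ratio)
    supports end-to-end validation without reanalysis downloads.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ncdf4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
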