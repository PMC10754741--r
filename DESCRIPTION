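Package: pm10risk
Title: Inhalation Health Risk Assessment for PM10-Bound Heavy Metals and PAHs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and probabilistic inhalation health-risk assessment
    for particulate-bound heavy metals and polycyclic aromatic hydrocarbons
    (PAHs) around industrial point sources such as opencast coal mines.
    Implements exposure concentration, hazard quotient and hazard index,
    lifetime cancer risk, benzo[a]pyrene toxic-equivalency (TEQ) and
    incremental lifetime cancer risk (ILCR), the geo-accumulation pollution
    index, PAH diagnostic-ratio source attribution, Monte Carlo uncertainty
    and sensitivity analysis, and conditional-probability-function (CPF)
    mapping of daily risk onto a geographic grid using forward and backward
    air-mass trajectories, including trajectory clustering. Ships a synthetic
    data generator for censored-lognormal speciated concentrations and
    directional trajectory bundles so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    jsonlite,
    geosphere,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
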