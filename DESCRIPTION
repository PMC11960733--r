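Package: baywater
Title: Long-Term Dissolved Oxygen and pH Trend Analysis for Estuarine
    Monitoring Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style pipeline for analysing multi-year,
    multi-station water-quality sensor records from estuarine fixed-site
    monitoring networks such as the Narragansett Bay Fixed Site Monitoring
    Network. Provides sensor ingest and unit conversion, iterative
    interquartile-range outlier screening with row-wise cascade, monthly
    climatologies and de-seasonalized anomaly trends with Durbin-Watson
    screening, a total-scale carbonate-system solver (TA, DIC, pH, pCO2)
    with Monte-Carlo error propagation, oxygen solubility, two-endmember
    conservative mixing curves for pH, driver-attribution budgets for
    dissolved-oxygen and pH trends, and a synthetic monitoring-network
    generator with a known truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    lmtest,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
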