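Package: winepi
Title: Dimensionless Flavour Modulators and Quality-Proxy Modelling for Pinot Noir Wine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models perceived wine quality from volatile and physiochemical
    composition using dimensional analysis. Chemical compounds are screened by
    odour activity value, grouped into five flavour modulators (fruity, herbal,
    floral, woody, other), combined into dimensionless Pi-terms under the
    Buckingham Pi theorem, and weighted by a geometric exponent schedule to give
    a power-law quality proxy calibrated against sensory panel ratings by grid
    search on Euclidean distance. Includes a synthetic-data generator emulating
    an 18-wine study design, SMOTE-style tabular augmentation with a dummy-class
    construction, and small feed-forward network regressors for validating the
    proxy on augmented data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
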