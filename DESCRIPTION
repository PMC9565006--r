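Package: vapequit
Title: Infoveillance of Quit-Vaping Mentions on Twitter Around the FDA
    Flavor Enforcement Policy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for measuring how mentions of quitting
    vaping on Twitter changed around the announcement (2 January 2020) and
    implementation (6 February 2020) of the US FDA flavor enforcement policy
    on cartridge-based flavored e-cigarettes. Provides readers for a minimal
    line-delimited JSON tweet corpus, keyword/geolocation/commercial
    filtering into three policy windows, from-scratch FP-growth frequent
    itemset mining and association-rule derivation of a quit-vaping lexicon,
    a variant-expanding quit classifier, per-period tweet and unique-user
    proportions with two-proportion z-tests, demographic breakdowns, and a
    seeded synthetic corpus generator with ground truth for end-to-end
    validation.
License: MIT
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
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
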