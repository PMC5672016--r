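Package: hormonet
Title: Neural-Network Surrogates and Genetic-Algorithm Optimization of
    Tissue-Culture Hormone Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models in vitro growth responses of Prunus rootstock explants
    (micro-shoot number, shoot length, callus weight, plantlet quality index)
    as functions of five plant-hormone concentrations (BAP, KIN, TDZ, IBA,
    NAA) with single-hidden-layer feed-forward neural networks trained by
    Levenberg-Marquardt, then searches the trained surrogates with a
    real-coded genetic algorithm to find optimal cytokinin-auxin
    combinations, and ranks hormone importance by variable sensitivity
    error/ratio (VSE/VSR). Ships the factorial dose-response tables as
    fixtures, regenerates replicate-level observations from the published
    means and standard errors, and provides a deterministic end-to-end
    pipeline with tidy outputs and ggplot2 diagnostics.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
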