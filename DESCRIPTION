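Package: ratioflux
Title: Daytime-to-Daily Vapor Flux Ratio Analysis for Eddy-Covariance Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the daily ratio of daytime to whole-day latent-heat flux
    (the daily RATIO) from half-hourly eddy-covariance records in the
    FLUXNET2015 dialect, quantifies the coupling of ecosystem flux, energy and
    matter variables with the daily RATIO by sub-interval binning and
    polynomial or random-forest curve fits, maps observations between places
    and ecosystems through those couplings, derives bootstrap distributions of
    temporal-trend coefficients per RATIO sub-interval, screens environmental
    drivers of the RATIO, and classifies the predicted surface-temperature
    effect of vegetation change by RATIO regime. Includes a synthetic
    flux-network generator with known ground truth so the whole pipeline is
    testable without data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
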