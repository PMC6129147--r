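Package: dubasclim
Title: Climatic Suitability Modelling for the Dubas Bug on Date Palms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for mapping current and
    future climatic suitability of the Dubas bug (Ommatissus lybicus) on
    date palms. Implements spatial climate-infestation regression (OLS with
    variance-inflation screening and geographically weighted regression),
    hotspot interpolation (inverse-distance weighting and ordinary kriging
    with a linear semivariogram), and a replicated ensemble species
    distribution model (maximum entropy, stepwise-AIC logistic regression
    and boosted regression trees) with bias-matched background sampling,
    Gaussian-kernel record weighting, max(sensitivity + specificity)
    thresholding, AUC/TSS validation and projection onto altered-climate
    scenarios. A synthetic-data module generates spatially autocorrelated
    climate stacks, a known true suitability surface, survey-biased
    occurrences and weather-station series so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    ggplot2,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
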