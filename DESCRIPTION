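Package: sistr
Title: Discriminating Chronic Heavy-Metal Stress in Rice from LAI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects chronic heavy-metal stress in paddy rice and separates it
    from abrupt stressors (pests, disease) and nutrition stress using two
    consecutive years of leaf-area-index (LAI) time series. Implements a
    reduced daily rice LAI simulator with a stress factor scaling gross
    assimilation, particle swarm optimisation of the stress factor against
    sparse observations, Sakoe-Chiba-banded dynamic time warping, per-pixel
    stress level and inter-annual temporal stability, local Moran's I of
    temporal stability on the rice mask, and the composite SIST index (the
    cube root of the product of the three normalised components). Ships a
    synthetic-scene generator with known per-pixel truth so the full pipeline
    is testable end to end.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    caret,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
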