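Package: lagtriad
Title: Triangulating Two-Wave Cross-Lagged Effects Against Spuriousness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives three families of standardized regression effects
    (adjusted cross-lagged, adjusted reverse, and difference-score effects)
    in closed form from two-wave correlation sextets, pools them with a
    two-step multilevel random-effects meta-analysis on the Fisher z scale,
    and classifies the pooled sign pattern as consistent with genuine
    decreasing effects or with spurious effects driven by correlated
    residuals and regression to the mean. Includes a latent common-cause
    generative model (with an optional occasion-state factor) that
    demonstrates how spurious cross-lagged patterns arise, and a synthetic
    meta-dataset generator emulating clustered effect sizes across
    heterogeneous samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    metafor,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
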