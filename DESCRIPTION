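Package: hemilat
Title: Hemispheric Lateralization of Alpha Oscillations and Subcortical
    Volume Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking hemispheric asymmetries in subcortical
    structure volumes to lateralized modulation of posterior alpha-band
    (8-13 Hz) power during covert spatial attention. Provides a synthetic
    cohort generator with known structure-function coupling, sliding-window
    Hanning-taper time-frequency power estimation with planar-gradiometer
    pair combination, per-sensor alpha modulation indices MI(alpha),
    hemispheric lateralization modulation HLM(alpha) overall and per task
    condition, lateralization volume indices, behavioral asymmetry scores,
    exhaustive AIC/BIC subset selection over volume-asymmetry regressors,
    and multivariate multiple regression of condition-wise HLM(alpha) with
    Hotelling and Wilks tests. All user-facing functions take and return
    tidy data frames so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
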