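Package: crossmed
Title: Cross Natural and Controlled Direct Effects with Two Binary Mediators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and partial identification of cross natural and
    controlled direct effects when two (possibly sequential) binary mediators
    lie between a binary exposure and a binary outcome. Provides g-formula
    plug-in estimators of the component potential-outcome means under no
    residual mediator-outcome confounding (with optional measured covariates),
    closed-form evaluation of tight nonparametric bounds on the cross effects
    under residual confounding, a linear-programming bounds engine over the
    canonical response-function partition of the unmeasured confounder,
    nonparametric bootstrap confidence intervals for estimates and bound
    endpoints, and synthetic-data generators including a COVID-19
    vaccine-trial mechanism with immunological mediators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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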