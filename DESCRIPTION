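Package: addhaz
Title: Additive Hazard Regression for Attributable-Risk Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semiparametric (constant-coefficient, Lin-Ying) and nonparametric
    (time-varying-coefficient, Aalen) additive hazard regression for
    right-censored cohort data, with closed-form estimating-equation fits,
    sandwich variances, cumulative baseline and excess cumulative hazards,
    ordinal trend tests, Cox-Snell residual goodness-of-fit via a built-in
    Nelson-Aalen estimator with a parametric-bootstrap envelope,
    covariate-profile survival curves and attributable-case estimates, and a
    synthetic cohort generator emulating a semiannual-visit screening design
    with midinterval event-time imputation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), survival, yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
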