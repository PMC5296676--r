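Package: thermoprop
Title: Thermal Inactivation Kinetics with Monte Carlo Uncertainty Propagation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step estimation of thermal inactivation kinetic parameters:
    decimal reduction times (D-values) from isothermal log-linear survivor
    curves, and the Bigelow secondary model parameters (D at a reference
    temperature and the z-value) from the temperature dependence of D.
    Delta-method confidence intervals, confidence and prediction bands for
    the secondary regression, and a nested Monte Carlo procedure that
    propagates the uncertainty of the per-temperature D-values into
    realistic confidence intervals for the secondary-model parameters via
    discretized-normal sampling. Includes a synthetic survivor-curve
    generator, a sampler validation routine and a sensitivity analysis over
    Monte Carlo sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
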