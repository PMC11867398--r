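Package: leadcea
Title: Early Economic Evaluation of Lead Screening and Chelation in Kidney
    Transplant Recipients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-level decision modelling of screening for high-normal
    plasma lead and oral DMSA chelation therapy in kidney transplant
    recipients. Provides a synthetic patient-level cohort generator,
    parametric survival fitting and extrapolation with conversion to
    per-cycle transition probabilities, a five-state time-inhomogeneous
    Markov cohort model with trapezoidal half-cycle correction,
    screening/chelation strategy overlays, cost-effectiveness analysis from
    societal and payer perspectives, deterministic and probabilistic
    sensitivity analyses with acceptability curves, five-year dynamic-cohort
    budget impact, and expected value of perfect, partial perfect and sample
    information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    flexsurv,
    survival,
    mgcv,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
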