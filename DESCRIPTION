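Package: tbpk
Title: Population Pharmacokinetics of First-Line Antituberculosis Drugs in TB/HIV Coinfection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects population pharmacokinetic analysis of
    rifampin, isoniazid, and pyrazinamide in adults treated with weight-band
    dosed fixed-dose-combination therapy, many of them coinfected with HIV-1.
    Provides the structural models (one-compartment first-order absorption
    with lag time, transit-compartment absorption into one- or two-compartment
    dispositions), allometric scaling on fat-free mass, HIV/antiretroviral
    covariate effects on clearance, censored-likelihood (M3) handling of
    observations below the limit of quantification, Laplace-approximation
    maximum likelihood with importance-sampling objective function values and
    Fisher-information precision, stepwise covariate selection by likelihood
    ratio, steady-state exposure metrics (Cmax, Tmax, AUC over the dosing
    interval), visual predictive checks, a synthetic cohort generator that
    emulates the study design, and the exposure/side-effect logistic
    regression analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
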