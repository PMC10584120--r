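Package: opilioOA
Title: Ocean-Acidification Effects on Snow Crab Embryos and Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for crossed ocean-acidification experiments on
    snow crab (Chionoecetes opilio) embryos and larvae. Fits the power-logistic
    (log-logistic) starvation-survival model to interval-censored daily
    mortality counts by maximum likelihood under factor-structured
    parameterizations and ranks the candidate set by AICc with Akaike weights.
    Provides from-scratch permutation multivariate statistics on morphometric
    tables (PERMANOVA, PERMDISP, ANOSIM, SIMPER, percent difference), the
    univariate ANOVA framework with Anderson-Darling/Levene assumption checks
    and a heteroscedasticity alpha-adjustment rule, reproductive bookkeeping
    (percent area yolk, fecundity, hatching success, hatch-count estimators),
    and a seawater carbonate-system solver (pH/DIC and TA/DIC pairs, saturation
    states). A synthetic-data generator emulates the crossed experimental
    design so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    car,
    nortest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    flexsurv,
    survival,
    jsonlite
Config/testthat/edition: 3
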