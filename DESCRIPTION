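Package: ineqdecomp
Title: Socioeconomic Inequality in Binary Health Outcomes: Concentration
    Indices and Their Decomposition for Complex Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures wealth-related inequality in binary health outcomes
    from complex survey microdata and decomposes it into covariate
    contributions. Implements weighted fractional (Lerman-Yitzhaki) ranks,
    concentration curves, the concentration index and the Erreygers
    concentration index for bounded outcomes with convenient-regression and
    cluster-robust standard errors, and the Wagstaff-van Doorslaer
    decomposition of the Erreygers index via partial effects from a
    weighted binomial GLM. Also provides survey-weighted prevalence and
    means with design-based confidence intervals, direct age
    standardization against the WHO world standard population, weighted
    wealth-quintile assignment, multi-year pooling of survey rounds, and a
    seeded generator of ENDES-like (Peruvian Demographic and Family Health
    Survey) synthetic microdata with a known socioeconomic gradient in
    abdominal obesity for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
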