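Package: obstaccess
Title: Closure Factors and Travel-Time Accessibility of Obstetric Units
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study the closure of hospital obstetric departments
    and its consequences for spatial accessibility. Builds an analysis
    cohort from coded two-year hospital-site registries (live births from
    procedure codes, department-based site identification, area-linked
    population density and fertility, a network-based competition
    covariate), fits and selects a multivariate logistic closure model
    (backward stepwise by AIC, generalized variance inflation factors,
    Benjamini-Hochberg adjusted p-values, LOWESS risk curves), and
    computes minimum travel-time surfaces to the nearest active facility
    under counterfactual regionalization scenarios. A seeded synthetic
    region generator (road network, area attributes, simulated closures)
    makes the full pipeline reproducible without confidential registry
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
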