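Package: soctau
Title: Soil Organic Carbon Turnover from Bomb Radiocarbon and Incubation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates soil organic carbon (SOC) turnover times from bulk-soil
    bomb-radiocarbon measurements (single-pool steady-state model driven by an
    atmospheric Delta-14C curve) and from laboratory incubation CO2 and
    dissolved organic carbon fluxes. Includes radiocarbon unit algebra with
    blank correction, a statistics-based site-selection procedure built on
    principal coordinates analysis of soil and landform covariates, blocked
    sequential (Type-I) ANOVA with order-permutation consistency screening for
    driver attribution, and a seeded synthetic-study generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
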