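Package: cyclehia
Title: Individual-Level Modelling of Commuter Cycling Uptake and Its Health
    and Carbon Impacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds seeded synthetic commuter populations on origin-destination
    (OD) pairs, fits logistic models of baseline cycling propensity as a
    function of route distance, hilliness and demographics, applies five
    cycling-uptake scenarios (Government Target Equality and Near Market,
    Gender Equality, Go Dutch, E-bikes), allocates new cyclists' former
    travel modes, and converts the resulting change in weekly physical
    activity (marginal MET hours) into premature deaths averted, discounted
    years of life lost, sickness-absence hours, monetised health benefits
    and avoided car CO2-equivalent emissions, disaggregated by demographic
    group.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
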