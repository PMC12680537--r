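Package: biomovr
Title: Global Biomass-Movement Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to compute, aggregate, bound and compare the biomass
    movement (biomass times annual distance travelled, Gt km per year) of
    animal groups and humans. Includes conservative uncertainty propagation
    over group hierarchies, estimation of annual travel distance from GPS
    tracking fixes, conversion of movement to locomotion energy via
    allometric cost-of-transport scaling, a two-step per-country human
    mobility estimator with gap-filling models, seeded synthetic-data
    generators with exact ground truth, and report assembly from a bundled
    set of published headline values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
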