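Package: chaetofeed
Title: Encounter Rates, Feeding Rates and Prey Electivity of Planktonic
    Ambush Predators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative tools for the trophic interaction between
    ambush-feeding chaetognaths and their copepod prey. Implements the
    Gerritsen-Strickler encounter kernel for calm water and the
    Rothschild-Osborn turbulence-augmented kernel, with calibration of the
    surface root-mean-square turbulent velocity from observed encounter
    enhancements and pluggable vertical turbulence profiles; gut-content
    feeding-rate estimation with a temperature-dependent digestion-time
    model; the Kimmerer-Slaughter diet electivity index with Beta
    Monte-Carlo confidence intervals; permutation-based two-factor
    PERMANOVA on Euclidean distances and BIOENV best-subset selection of
    environmental correlates; and seed-deterministic synthetic generators
    for station grids, CTD profiles, gut surveys and diet/habitat
    composition tables so the full pipeline runs without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
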