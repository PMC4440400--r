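Package: soxtherm
Title: Stoichiometry and Energy Conservation Efficiency of
    Chemolithoautotrophic Sulfur Oxidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds mass- and charge-balanced generalized reaction
    equations for autotrophic oxidation of reduced sulfur compounds
    (sulfide, thiosulfate) coupled to reduction of a terminal electron
    acceptor (oxygen, nitrate via denitrification or DNRA) and to CO2
    fixation by the Calvin or reverse tricarboxylic acid cycle.  The
    reaction family is parameterized by the zero-valent-sulfur versus
    sulfate product partition (x) and the fraction of the reduced
    sulfur pool spent on energy generation (y).  Provides Gibbs free
    energies at biochemical standard or user conditions from a
    versioned formation-energy table, the traditional and the
    carrier-explicit energy conservation efficiencies together with
    their factorization into partial efficiencies and minimum bounds,
    inverse solvers that recover the full stoichiometry from limited
    rate measurements, sensitivity and niche-band analysis, and
    regeneration of a reference strain comparison table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
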