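Package: fsdiet
Title: Individual Diet Modeling of Free Sugar Intakes by Linear Programming
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying free sugar intakes in 7-day dietary survey
    data and for rebalancing individual diets by linear programming.
    Annotates a food composition table with free sugar content using the
    recipe/converting-factor method, scores diet quality (solid energy
    density, variety, MAR, MER, PANDiet), screens energy under-reporters
    (Goldberg method), classifies individuals against the WHO 10 percent
    free-sugar energy threshold, and designs for each individual an
    iso-energy diet meeting 33 nutrient recommendations while departing
    least from the observed diet. Binding constraints are diagnosed through
    LP dual values. A seed-reproducible survey simulator emulating the
    statistical structure of the French INCA2 adult survey makes every
    pipeline stage testable without access to the original microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
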