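Package: helicomb
Title: Helical Lattice and Honeycomb Interface Analysis of Death-Fold Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the helical architecture of death-fold
    (pyrin- and CARD-domain) protein filaments from atomic or pseudo-atomic
    coordinates. Fits the filament axis and screw operator (twist and rise
    per subunit, axial point-group order, strand count) from a multi-chain
    model, builds ideal filaments from a protomer and helical parameters,
    extracts the honeycomb neighborhood of a protomer and classifies its six
    contacts into the conserved Type 1/2/3 interface classes, measures
    base-layer subunit counts and rim diameters, and scores the steric
    compatibility of a monomer rigidly threaded into a foreign filament
    lattice (clash and contact counts with top/bottom half sums). Includes a
    deterministic generator of coarse-grained six-helix-bundle protomers and
    idealized filament fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
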