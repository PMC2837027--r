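Package: duplexnn
Title: Nearest-Neighbour Thermodynamic Models for DNA Duplex
    Hybridization Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of hybridization free energies for perfect-match
    DNA duplexes with thermodynamic nearest-neighbour models built from
    doublet (two adjacent base pairs) or triplet (three adjacent base
    pairs) stacking interactions.  Model parameters are fitted to
    experimental free energies by minimum-norm least squares, and models
    are assessed with a repeated random-split evaluation protocol
    (Pearson correlation and root mean squared error on held-out
    duplexes).  Includes a reader/writer for a 15-column comma-separated
    duplex benchmark format, secondary-structure comparison measures
    (similarity index, base-pair sensitivity, positive predictive value
    and F-measure), a synthetic-data generator with known ground-truth
    parameters, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
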