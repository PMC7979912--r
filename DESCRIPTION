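Package: crisscross
Title: Nucleation Control in Crisscross Polymerization of DNA Slats
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models and design tools for crisscross polymerization of highly
    coordinated DNA slat monomers. Computes kinetic Tile Assembly Model (kTAM)
    free-energy landscapes and spontaneous-nucleation barriers for square-tile,
    hexagonal-tile and crisscross-slat architectures; simulates and fits a
    stochastic seeded-growth model for ribbon elongation with stalling and
    termination; quantifies spontaneous nucleation rates from agarose-gel
    densitometry with detection-limit censoring; and designs complete
    single-stranded DNA slat sets (domain layouts, orthogonal sequences,
    brushes, sticky ends, genome-folding nucleators) with FASTA and plate
    exports. Includes a synthetic-data generator emulating TEM ribbon-length
    samples and gel lanes so every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
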