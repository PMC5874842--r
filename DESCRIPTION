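Package: asdscreen
Title: In Silico Drug-Polymer Miscibility Screening for Amorphous Solid
    Dispersions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for early-stage excipient screening of spray-dried
    amorphous solid dispersions. Estimates Hansen solubility parameters
    from structural group contributions (Fedors and Hoftyzer-van Krevelen
    schemes, including copolymer averaging), derives Flory-Huggins
    interaction parameters and free-energy-of-mixing phase diagrams with
    spinodal compositions, applies the Greenhalgh difference criterion and
    Bagley-plot distances, classifies calorimetric/diffraction screening
    observations into glass-solution, amorphous-phase-separated and
    residually crystalline categories, ranks candidate polymers with
    top-3 concordance scoring against a reference method, and compares
    screening methods by principal component analysis. A seeded synthetic
    data generator emulates modulated-DSC thermograms, powder diffraction
    patterns and full screening campaigns with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
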