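Package: pulchkin
Title: Pulcherrimin Production Kinetics, Reporter Gating, and DNase I
    Footprinting Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of pulcherrimin regulation in Bacillus
    subtilis at synthetic scale: Gompertz-based pulcherrimin production
    kinetics anchored to the exponential-to-stationary growth transition
    (T0), flow-cytometry percent-GFP-positive gating against a negative
    control, and differential peak-height analysis of fluorescent DNase I
    footprinting electropherograms with ladder-based size calibration and
    protection/hypersensitivity region calling in zero-free promoter
    coordinates. Includes seeded synthetic-data generators with known
    ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
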