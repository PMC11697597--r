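Package: gasfx
Title: Simulated Dosimetric Impact of Rectal Gas in Carbon-Ion Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic-data pipeline for quantifying how residual bulky rectal
    gas perturbs scanned carbon-ion radiotherapy dose to the prostate clinical
    target volume, rectum, and rectal wall. Generates seeded pelvic phantom
    pairs (planning CT and gas-distended CT) with a known ground-truth
    deformation field, computes RBE-weighted dose with a simplified
    pencil-beam engine using the modified microdosimetric kinetic model,
    performs rigid and deformable registration with dose warping, composes
    fractionation scenarios for 0 to 12 gas-affected fractions, evaluates
    dose-volume-histogram changes, extracts rectal-gas indicators from
    digitally reconstructed radiographs, and relates indicators to dose
    changes with correlation and signed-rank statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
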