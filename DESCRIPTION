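Package: celldose
Title: Cellular Dosimetry and Radiobiology for Auger-Electron Emitters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Subcellular absorbed-dose assessment and radiobiological
    analysis for DNA-targeted Auger- and conversion-electron emitters such
    as 99mTc. Converts gamma-counter uptake measurements into
    compartment-resolved time-integrated activities, computes nucleus and
    cytoplasm absorbed doses with the MIRD cellular S-value formalism, and
    provides a continuous-slowing-down-approximation Monte Carlo engine for
    electron energy deposition in a concentric-sphere cell phantom.
    Includes clonogenic survival-curve fitting with the single-hit
    exponential model, IC50 and relative biological effectiveness (RBE)
    estimation with uncertainty propagation, DNA-damage endpoint summaries
    (gamma-H2AX foci, micronuclei), and seed-deterministic synthetic-data
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
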