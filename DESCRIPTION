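Package: pram
Title: Multicriteria Resource Allocation Modelling for Postnatal Care Redesign
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision support for redesigning routine postnatal care services.
    Combines multicriteria decision analysis (MCDA) with programme budgeting
    and marginal analysis (PBMA): care-pathway descriptions for categories of
    mothers and babies are scored against the five Institute of Medicine
    quality domains through an impact matrix with normalisation to a 0-100
    scale, costed along hospital (staff versus bed/infrastructure) and
    community pathways, and compared option-against-option with equity-impact
    -plane classification. Includes an acuity-transition sub-model linking
    hospital length of stay to the discharge case mix, deterministic
    sensitivity analysis with proportional weight renormalisation, plain-text
    bundle input/output, a seeded fixture generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
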