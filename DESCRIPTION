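Package: trichodiel
Title: Diel Physiology of a Trichodesmium Trichome with Dynamic Membrane
    Oxygen Permeability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained diel simulation of a Trichodesmium trichome
    coupling photosynthetic electron transport, carbon fixation,
    photorespiration, respiratory protection, nitrogen fixation, iron
    allocation among intracellular pools, and physical oxygen exchange
    through a cylindrical cell envelope whose relative oxygen diffusivity
    is either fixed or regulated by intracellular oxygen. Includes
    growth-maximization calibration of the four free rate parameters,
    model-skill metrics (coefficient of determination and reliability
    index), a synthetic diel observation generator, and scenario engines
    for iron gradients, external-oxygen and permeability-amplitude scans,
    permeability-mode comparison, and photorespiration substitution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
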