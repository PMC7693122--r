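Package: gelmetrics
Title: Multiscale Characterization of Semi-Interpenetrating Network Hydrogels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multiscale structural and transport
    characterization of agarose-based semi-interpenetrating-network
    hydrogels. Fits generalized Maxwell models to oscillatory frequency
    sweeps and derives crosslink density and rubber-elasticity mesh size;
    converts tracer mean-square-displacement traces to viscoelastic moduli
    through the generalized Stokes-Einstein relation; fits the semi-infinite
    erfc diffusion solution to solute concentration profiles for effective
    diffusivity and partition coefficients; fits single-component 3-D FCS
    autocorrelation curves and mono-exponential TCSPC decays; extracts
    turbidity wavelength exponents and maps them to correlation lengths;
    and quantifies pore structure in micrographs by maximum-entropy
    thresholding, particle analysis and skeleton branch analysis. A seeded
    synthetic-data module generates every input modality with known ground
    truth so the whole pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
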