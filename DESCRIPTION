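Package: octsynth
Title: Synthetic Scanning Simulation of Spectral-Domain OCT Image Formation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates spectral-domain optical coherence tomography (OCT)
    image formation by synthetic scanning: from a single scattered-field
    computation under normally incident plane-wave illumination, the
    focussed, laterally scanned acquisition (A-scans and B-scans) is
    synthesized via angular-spectrum phase manipulation, single-mode fiber
    coupling, and spectral Fourier reconstruction. Includes analytic
    point-scatterer forward models, a multi-slice split-step beam
    propagation solver with a first-Born return path for scattering
    phantoms, direct (non-synthesized) reference simulators of a scanned
    focussed beam, seeded phantom generators, and depth-resolved error
    metrics and field-discrepancy statistics for quantifying the
    approximation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
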