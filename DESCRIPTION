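Package: photophyskit
Title: Photophysics of Solvatochromic Dyes and Nanoparticle Quenching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis chain for the photophysical characterization of
    fluorescent dyes interacting with metallic nanoparticles: spectral
    band descriptors and unit conversions, solvatochromic dipole-moment
    estimation (Lippert-Mataga and Reichardt methods), relative
    fluorescence quantum yields, oscillator strength and transition
    dipole moments, Stern-Volmer superquenching and Perrin active-sphere
    analysis, metal-enhanced fluorescence curves, emission/plasmon
    overlap diagnostics, and nanoparticle post-processing (Debye-Scherrer
    crystallite sizing from XRD, surface plasmon band metrics). Includes
    seeded synthetic-data generators so every stage is testable without
    instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
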