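Package: isoct
Title: Inverse Spectroscopic Optical Coherence Tomography Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for inverse spectroscopic optical coherence
    tomography (ISOCT) of strongly scattering, pigmented biological samples
    such as reef-building corals. Converts raw visible-band (520-720 nm)
    spectral-domain OCT interferograms into wavelength-resolved backscatter
    cubes, detects sample surfaces, fits Beer-Lambert attenuation, and
    decomposes the total attenuation spectrum into scattering and
    chlorophyll-a absorption under a Whittle-Matern continuous random medium
    model, yielding maps of the mass-fractal dimension D, the scattering
    anisotropy g, scattering and absorption coefficients, and chlorophyll-a
    areal density. Ships a forward simulator of synthetic OCT volumes from
    layered phantoms with known ground truth, plus Mie-theory standards, so
    every inversion stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
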