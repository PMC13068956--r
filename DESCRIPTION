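Package: epimech
Title: Quantification Pipelines for Epithelial Monolayer Mechanics and Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipelines for studying mechanical homeostasis in
    epithelial monolayers such as the retinal pigment epithelium (RPE).
    Implements Hertzian nanoindentation curve analysis with contact-point
    detection and cantilever-compliance correction, storage and loss moduli
    from oscillatory indentation, Lorentzian fitting of Brillouin
    Stokes/anti-Stokes spectra with z-profile peak/plateau analysis and
    core-interstitium statistics on raster shift maps, monolayer image
    morphometrics (cell density, height, shape factor, junctional and
    nuclear intensity ratios, extrusion counting, microvilli length),
    classification of photoreceptor outer segment fragments as internalised
    or bound from 3D stacks, and paired replicate statistics. Seeded
    synthetic-data generators with attached ground truth make every pipeline
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    minpack.lm,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
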