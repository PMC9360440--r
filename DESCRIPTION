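Package: sheetsim
Title: Simulation and Characterization of Light-Sheet Microscopy Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates Gaussian, flat-top, multi-Bessel square-lattice and
    hexagonal-lattice light sheets from back-pupil field definitions through
    the spatial-light-modulator and annular-mask beam-forming chain; propagates
    beams along the sheet axis and forms dithered excitation profiles; builds
    vectorial Richards-Wolf detection point spread functions, overall PSFs and
    optical transfer functions; quantifies beams (axial FWHM, main-lobe width,
    optical sectioning, OTF support, propagation length, h90, power density);
    renders noisy three-dimensional point-emitter acquisitions; estimates
    resolution by Fourier plane correlation; and restores or fuses images by
    Richardson-Lucy deconvolution, Wiener filtering and OTF-weighted spectral
    fusion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
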