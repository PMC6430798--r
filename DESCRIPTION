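Package: specklescope
Title: Compressive 3D Super-Resolution Speckle Microscopy Simulation and
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates saturated-excitation 3D speckle point-spread
    functions by random-pupil Fourier optics, forms single 2D raster-scan
    images of voxelized 3D fluorescent objects, and recovers the 3D object
    either by plane-by-plane Wiener deconvolution or by FISTA l1
    compressed sensing. Includes synthetic phantoms (beads, dense layers,
    filaments), Poisson noise, a resolution and speckle-orthogonality
    metrology suite (FWHM, axial correlation curves, spectral support,
    reconstruction SNR), and multi-page TIFF stack input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
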