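# specklescope

Simulation and reconstruction toolkit for **compressive 3D
super-resolution speckle microscopy**: imaging a 3D fluorescent sample
beyond the diffraction limit from a **single 2D raster scan** under
saturated excitation with a 3D speckle pattern.

## The method in brief

A coherent wavefront with random pupil phases focuses into a fully
developed 3D speckle — exponential intensity statistics
ρ(I) = e^(−I/⟨I⟩)/⟨I⟩, unit contrast, transverse grain λ/(2NA) and axial
grain 2nλ/NA². Raster-scanning this pattern across a sample while
integrating the fluorescence yields one 2D image in which every object
plane is cross-correlated with the speckle present at its own depth:

    b(r₀) = Σ_z Σ_r O_z(r) · F_z(r − r₀)

Because speckle planes further apart than one axial grain are
statistically orthogonal, each object plane can be demixed from the
single scan — by plane-by-plane **Wiener deconvolution**, or by solving
the compressed-sensing problem

    min_x ‖A x − b‖² + λ‖x‖₁

with **FISTA**, where A is the speckle projection operator. Saturating
the fluorophores (emission probability 1 − e^(−s) per pulse, speckle
average ⟨F⟩ = ⟨s⟩/(⟨s⟩+1)) preserves the dark optical vortices while
flattening bright grains, sharpening the effective pattern: transverse
resolution scales as δx = (λ/2NA)/√(1+s) and the axial decorrelation
length shrinks by ≈√2 at ⟨s⟩ = 3.7.

The package provides, as plain R functions: Fourier-optics speckle
simulation with statistics validation, the saturation model and
saturation-curve fitting, ground-truth phantoms (beads, sparse point
sets, dense layers, filaments), the scan-image forward model with
Poisson noise, Wiener and FISTA reconstructions, a resolution metrology
suite (FWHM, axial correlation curves, spectral support, reconstruction
SNR), multi-page TIFF I/O with JSON sidecars, and a thin CLI
(`inst/cli/specklescope`) with `spsf`, `scan`, `wiener`, `fista`,
`metrics` and `demo` subcommands.

## Worked example

```r
library(specklescope)

## optical configuration: NA 0.77 objective, 532 nm, oil-like medium,
## 100 nm scan pixels, 25 planes spaced 250 nm
cfg <- optical_config(wavelength = 532, na = 0.77, medium_index = 1.515,
                      pixel_size_xy = 100, grid_shape = c(256, 256),
                      z_planes = seq(-3000, 3000, by = 250))
grain_sizes(cfg)
#> $transverse      345.45 nm
#> $axial          2718.77 nm

## simulate the 3D speckle excitation and its saturated response
I   <- intensity(propagate(build_pupil(cfg, seed = 1)))
lin <- fluorescence_response(I, s_mean = 0)    # linear excitation
sat <- fluorescence_response(I, s_mean = 1.4)  # saturated, <s> = 1.4
check_rayleigh(I[, , reference_plane(cfg)])
#> $contrast      1.00202      (fully developed: contrast ~ 1)
#> $pdf_distance  0.00181      (exponential intensity statistics)

## a single in-focus point source, scanned once in 2D
ph <- beads(c(256, 256, 25), matrix(c(128, 128, 13), 1),
            voxel_size = c(100, 100, 250))
img_lin <- scan_image(ph, lin)
img_sat <- scan_image(ph, sat)

## axial demixing resolution: Wiener peak profile across all planes
wp <- wiener_params(rel_floor = 1e-7)
fw_lin <- profile_fwhm(axial_response_profile(img_lin, lin, wp), 250)
fw_sat <- profile_fwhm(axial_response_profile(img_sat, sat, wp), 250)
cat(sprintf("axial FWHM  linear: %.0f nm   saturated: %.0f nm   ratio: %.2f\n",
            fw_lin, fw_sat, fw_lin / fw_sat))
#> axial FWHM  linear: 2454 nm   saturated: 1329 nm   ratio: 1.85
```

The linear axial width tracks the axial speckle grain (2.7 µm); moderate
saturation (⟨s⟩ = 1.4) narrows the axial response by close to a factor
of two. The transverse bookkeeping of the same experiment:

```r
0.514 * 532 / 0.77                 # diffraction-limited FWHM: 355 nm
resolution_bound(532, 0.77, 3.7)   # RESOLFT bound at s = 3.7: 159 nm
bead_corrected_width(147, 100)     # 147 nm bead image, 100 nm bead:
#> 107.7                           # ~108 nm effective PSF, 3.3x beyond
                                   # the 355 nm diffraction limit
```

Sparse 3D recovery from the same single image, with exact ground truth:

```r
ph  <- random_sparse(c(64, 64, 8), K = 10, seed = 7, min_separation = 600,
                     voxel_size = c(150, 150, 1000))
img <- scan_image(ph, resp)        # resp: a 64 x 64 x 8 response stack
res <- fista(img, resp, fista_params(lambda_reg = 0.02, n_iter = 500))
res$estimate                       # all 10 sources, ~1% amplitude error
```

See `vignettes/speckle-microscopy.Rmd` for the models, parameter
conventions, numerical choices, and what the synthetic tests do and do
not establish.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch at run time, the axial-narrowing target: it
simulates 10 independent 256×256×25-plane speckle responses (NA 0.77,
λ = 532 nm, n = 1.515, 250 nm plane spacing), forms the in-focus
point-source scan image for the linear and ⟨s⟩ = 1.4 saturated
responses on matched seeds, Wiener-deconvolves each image against every
plane, and writes the median ratio of the axial FWHMs of the two peak
profiles as JSON.
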