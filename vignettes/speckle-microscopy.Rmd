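---
title: "Compressive 3D super-resolution speckle microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressive 3D super-resolution speckle microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specklescope)
```

## The imaging model

A speckle scanning microscope illuminates a fluorescent sample with a
*3D speckle pattern* — the random interference structure produced by
focusing a wavefront with independent uniform pupil phases — and raster
scans it transversely while collecting the total fluorescence on a single
detector. Each transverse plane of the 3D sample is thereby
cross-correlated with the speckle pattern present at its own depth, and
the single 2D image is the sum of all plane contributions:

$$ b(\mathbf r_0) \;=\; \sum_z \sum_{\mathbf r} O_z(\mathbf r)\,
   F_z(\mathbf r - \mathbf r_0), $$

where $O_z$ is the fluorophore density of plane $z$ and $F_z$ the
excitation (or saturated-fluorescence) response at that plane. Two
statistical facts make the 3D object recoverable from this single 2D
scan:

1. **Speckle orthogonality.** Transverse speckle patterns at axial
   separations beyond one axial grain, $\delta z \ge 2 n \lambda /
   \mathrm{NA}^2$, are statistically uncorrelated. Deconvolving $b$
   against the response of plane $z$ therefore extracts the sources of
   plane $z$ while the other planes contribute only a low background.
2. **Saturation.** With pulses much shorter than the fluorescence
   lifetime, the emission probability per pulse is $F = 1 - e^{-s}$ with
   saturation parameter $s \propto$ local intensity. Saturation flattens
   the bright speckle grains but preserves the dark optical vortices, so
   the *effective* pattern acquires sharper features than the
   diffraction limit: resolution scales as $\delta x = (\lambda /
   2\mathrm{NA}) / \sqrt{1+s}$, and the axial decorrelation length
   shrinks as well.

The package simulates this entire chain — pupil, 3D speckle, saturation,
phantom, scan image, noise — and reconstructs the object by plane-by-plane
Wiener deconvolution or by FISTA $\ell_1$ minimisation, with a metrology
suite for the resolution claims.

## Speckle simulation

`build_pupil()` draws i.i.d. uniform phases on the numerical-aperture
disk $|k_\perp| \le \mathrm{NA} \cdot 2\pi/\lambda$ (scaled by an
optional iris fraction) and `propagate()` applies angular-spectrum
propagation with the full non-paraxial axial wavenumber
$k_z = \sqrt{(2\pi n/\lambda)^2 - k_\perp^2}$. At NA 0.77 the paraxial
approximation visibly distorts axial correlation lengths, which is why
the exact $k_z$ is used. Propagation is a pure phase multiplication, so
per-plane energy is conserved exactly (checked to $10^{-6}$ relative in
the tests).

Choices a user should know about:

* **Periodic statistics.** Fields live on a periodic grid and all
  correlations are circular. The finite illumination envelope of a real
  speckle spot (5–10 µm) is *not* simulated: the statistical claims the
  package tests are envelope independent, and an envelope would add one
  more parameter to every experiment.
* **Sampling.** The transverse pixel must satisfy the intensity Nyquist
  bound `pixel_size_xy <= lambda / (4 NA)`; the constructor enforces it.
* **Normalisation.** Intensity stacks are normalised to unit mean over
  the *reference plane* (the plane closest to $z=0$). The saturation
  parameter `s_mean` refers to that plane, the way a pulse energy refers
  to the focal spot. Normalising per plane instead would distort axial
  comparisons; normalising over the volume would make `s_mean` depend on
  the simulated z-range. This convention is the package's own choice.
* **Vectorial mode.** Scalar fields are the default everywhere. The
  optional `circular_vectorial` mode adds an axial component
  $E_z \propto \sin\theta\, e^{i\varphi_k}$ with $\sqrt{\cos\theta}$
  apodization for circular input polarization. It reproduces the
  qualitative fact that the axial field fills most scalar intensity
  zeros; it is *not* a full vectorial focusing (Richards–Wolf)
  computation, and no quantitative claim rests on it.
* **Frequency convention.** Pupils are stored with DC at the array
  centre for readability; all internal FFTs re-order as needed.

`check_rayleigh()` verifies the fully developed character of a simulated
plane: unit contrast (std/mean) and a small Kolmogorov distance between
the empirical intensity distribution and the exponential law
$\rho(I) = e^{-I/\langle I\rangle}/\langle I\rangle$.

## Saturation

`fluorescence_response()` applies $F = 1 - \exp(-s_{\text{mean}}
I/\langle I\rangle_{\text{ref}})$ voxelwise; `s_mean = 0` is the
documented linear limit and returns the normalised intensity itself, so
linear and saturated responses share one scale. The closed-form speckle
average $\langle F\rangle = \langle s\rangle/(\langle s\rangle + 1)$
(`mean_fluorescence()`) is validated against a Monte-Carlo average over
exponential intensities, and `fit_half_saturation()` recovers the
half-saturation pulse energy from an energy–signal curve, the standard
calibration experiment on a thin dye layer. The two-level-dye temporal
integral is collapsed to its short-pulse limit throughout; no pulse-shape
library is provided because all quantitative analysis uses this same
approximation.

## Forward imaging and noise

`scan_image()` computes the per-plane circular cross-correlation
spectrally; the identical code path implements the measurement operator
$A$ of the inverse problem (`forward_A()`), so the forward model, its
adjoint and the Wiener filter are bit-consistent with one another.
Correlation (not convolution) is the canonical convention — the scanned
excitation samples the object at $\mathbf r = \mathbf r_0 + \mathbf u$ —
and the spatial reversal it implies is absorbed inside the
reconstructions so estimates come out in object coordinates. The scan
step equals the response pixel size; resampling between grids is out of
scope. `apply_noise()` scales an image to a photon budget, adds a
constant background, and draws Poisson counts.

## Wiener reconstruction

`wiener_plane()` divides the image spectrum by each response-plane
spectrum with a flat noise density:
$\hat O_z = \mathcal F^{-1}[ B \hat F_z / (|\hat F_z|^2 + N_0) ]$.
One scalar $N_0$ regularises everything, mirroring the single visually
tuned parameter of practical deconvolution. The reproducible default is
`rel_floor = 1e-3` times the plane's strongest **off-DC** spectral power.
Referencing the raw spectral maximum would anchor $N_0$ to the DC bin,
which only encodes the mean response level and, under saturation, exceeds
every structural frequency by orders of magnitude — the filter would then
be uniformly over-regularised. For noiseless synthetic data the metrology
uses `rel_floor = 1e-7`, the whitening limit in which the measured
resolution saturates (results are insensitive to this value over several
decades; it corresponds to tuning the parameter for best resolution on a
clean image). Outputs are unclipped by default so reconstruction noise
stays visible.

## FISTA reconstruction

`fista()` solves $\min_x \|Ax - b\|^2 + \lambda \|x\|_1$ with the
Beck–Teboulle accelerated proximal gradient method. The objective carries
no $\tfrac12$ factor, so the gradient is $2A^{\mathsf T}(Ax-b)$ and the
Lipschitz constant is $L = 2\sigma_{\max}(A)^2$. Because $A$ is diagonal
in the 2D frequency domain, $\sigma_{\max}^2 = \max_k \sum_z |\hat
F_z(k)|^2$ is available in closed form; a power-iteration estimator is
provided and cross-checked against it.

Numerical choices:

* **Mean subtraction (`demean`, default on).** The identity
  $b - \bar b = \sum_z O_z \star (F_z - \bar F_z)$ holds exactly, and
  solving the demeaned system removes the DC row of $A$ whose spectral
  weight $(N\langle F\rangle)^2$ exceeds the structural frequencies by a
  factor of order the pixel count. Without it the auto step $1/L$ is that
  same factor too small and hundreds of thousands of iterations would be
  needed; with it, K-sparse recovery converges in a few hundred. Fixed
  points of the demeaned problem coincide with the original ones up to
  per-plane constants, which the $\ell_1$ penalty sets to zero.
* **Auto step.** `step = "auto"` uses $1/L$; a numeric step larger than
  $1/L$ is rejected unless explicitly overridden (the override exists to
  reproduce fixed-small-step regimes such as $t = 10^{-7}$).
* **Monotone safeguard.** Plain FISTA is not monotone; when the
  objective increases, the momentum is restarted and a plain ISTA step is
  taken from the previous iterate, which for $t \le 1/L$ guarantees a
  non-increasing trace without changing the fixed points.
* **Sparsity weight.** Recovery experiments in the tests use
  $\lambda = 0.01 \cdot 2\|A_\delta^{\mathsf T} b_\delta\|_\infty$ (1% of
  the null threshold of the demeaned system): large enough to sparsify in
  a few hundred iterations, small enough that the soft-threshold
  amplitude bias stays near 1%. `select_lambda_rmse()` offers the
  RMSE-against-truth grid search for simulation studies only; user-facing
  reconstruction never sees the truth.
* **Nonnegativity** is off by default (the plain $\ell_1$ objective has
  no such constraint) but available, since fluorophore density is
  physically nonnegative. Only the voxel basis is supported.

## Metrology

* `profile_fwhm()` interpolates the half-maximum crossings around the
  unique global peak, with the profile minimum as baseline — invariant
  under value rescaling and offset.
* `axial_correlation_curve()` records the mean-subtracted, normalised
  cross-correlation peak versus defocus. Mean subtraction is part of the
  curve's definition: the saturated response has a large DC component
  whose trivial correlation would otherwise mask the narrowing that
  saturation produces.
* `axial_response_profile()` is the Wiener peak value per plane for an
  in-focus point-source image: the axial demixing resolution observable.
* `spectral_support()` reports the largest radial frequency whose
  azimuthally averaged power exceeds `floor_fraction` (default $10^{-3}$,
  always reported with the value) of the first off-DC bin.
* `bead_corrected_width()` removes a bead diameter from a measured image
  width via $W = \sqrt{d^2 + w^2}$.
* `reconstruction_snr()` compares an estimate against the phantom's exact
  ground truth (never against rendered images); a zero-background
  reconstruction reports the sentinel `Inf`.

## What the synthetic world does and does not establish

The generator reproduces the *statistical* properties the method relies
on: exponential intensity statistics, unit contrast, diffraction-set
grain sizes, axial decorrelation, and the saturation law. Defaults match
the stated experimental conditions: $\lambda = 532$ nm, NA $= 0.77$,
$n = 1.515$, 50–150 nm pixels, 250–1000 nm plane spacings, and mean
saturation parameters 1.4 and 3.7. It does not emulate optical
aberrations, index-mismatch, SLM pixelation, scan distortion, the finite
speckle envelope, photobleaching, or realistic organelle morphology
(`filaments()` is a stress-test shape, not a cytoskeleton model). A green
test therefore establishes that the algorithms behave as the theory
predicts on statistically faithful speckle — not that an instrument will
reach the same numbers. Measured widths in an experiment are
additionally broadened by bead size and aberrations; simulated axial
narrowing ratios here come out near 1.8 where the idealised prediction
is 2, with the residual gap attributable to the finite simulated z-range
and grain statistics rather than to a tunable parameter.

## Degenerate inputs and tie-breaks

Zero response planes, all-zero statistics planes, constant correlation
planes, truncated FWHM peaks and non-bracketing saturation fits raise
errors (or set an ill-conditioning flag) rather than returning silently
wrong numbers. Where an argmax is reported, the first of exactly tied
voxels in column-major order is used; simulated speckle makes exact ties
measure zero in practice.

## Known limitations

* Circular boundary conditions everywhere; a zero-padded linear mode for
  user-supplied finite PSFs is not implemented.
* The vectorial mode is qualitative (see above).
* The TIFF reader covers uncompressed 8/16-bit unsigned and 32-bit float
  stacks only — sufficient for the package's own round trips and typical
  acquisition output, not a general TIFF implementation.
* Depth-of-field scaling with the speckle-spot size, inverted-contrast
  and non-Rayleigh speckles are outside the model.
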