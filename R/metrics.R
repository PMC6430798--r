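#' Full width at half maximum of a 1D profile
#'
#' FWHM by linear interpolation of the two half-maximum crossings around
#' the unique global peak. The profile's minimum is taken as the baseline
#' zero, so the measure is invariant under rescaling and translation of the
#' profile values.
#'
#' @param profile Numeric vector with a unique global maximum away from
#'   both ends.
#' @param spacing Sample spacing (nm per sample).
#' @return FWHM in the units of `spacing`.
#' @export
profile_fwhm <- function(profile, spacing = 1) {
  p <- as.numeric(profile)
  n <- length(p)
  stopifnot(n >= 3, spacing > 0)
  i_max <- which.max(p)
  if (sum(p == p[i_max]) > 1)
    stop("profile has no unique global maximum", call. = FALSE)
  if (i_max == 1 || i_max == n)
    stop("peak at profile boundary (truncated)", call. = FALSE)
  base <- min(p)
  half <- base + (p[i_max] - base) / 2
  left_ok <- which(p[1:i_max] <= half)
  if (length(left_ok) == 0)
    stop("no half-maximum crossing on the left (peak truncated)", call. = FALSE)
  li <- max(left_ok)  # p[li] <= half < p[li + 1]
  u_left <- li + (half - p[li]) / (p[li + 1] - p[li])
  right_ok <- which(p[i_max:n] <= half)
  if (length(right_ok) == 0)
    stop("no half-maximum crossing on the right (peak truncated)", call. = FALSE)
  ri <- i_max + min(right_ok) - 1  # p[ri - 1] > half >= p[ri]
  u_right <- (ri - 1) + (half - p[ri - 1]) / (p[ri] - p[ri - 1])
  (u_right - u_left) * spacing
}

#' Remove the bead size from a measured image width
#'
#' A finite bead of diameter `d` imaged by a PSF of width `w` appears with
#' width `W = sqrt(d^2 + w^2)`; this inverts that relation to recover the
#' effective PSF width `w = sqrt(W^2 - d^2)`.
#'
#' @param W Measured image FWHM (nm), `W >= d`.
#' @param d Bead diameter (nm).
#' @return Corrected width `w` (nm).
#' @export
bead_corrected_width <- function(W, d) {
  stopifnot(W >= 0, d >= 0)
  if (W < d) stop("measured width smaller than bead diameter", call. = FALSE)
  sqrt(W^2 - d^2)
}

#' Axial cross-correlation curve of a response stack
#'
#' For each plane, computes the mean-subtracted, normalised circular
#' cross-correlation with the reference plane and records the correlation
#' peak (maximum over transverse shifts). The peak-versus-defocus curve
#' quantifies speckle orthogonality: it equals 1 at zero offset and decays
#' over roughly one axial grain length `2 n lambda / NA^2`. Mean
#' subtraction is essential under saturation, where the response acquires a
#' large DC component that would otherwise mask the narrowing of the
#' curve.
#'
#' @param response Response stack `c(ny, nx, nz)` with `nz >= 2`.
#' @param ref_plane Reference plane index (default: middle plane).
#' @param z_planes Axial positions (nm); taken from the stack's `config`
#'   attribute when present, else unit spacing.
#' @return An object of class `correlation_curve`: `dz` (offsets, nm),
#'   `peak_value`, and `fwhm` (nm; `NA` when the curve does not cross its
#'   half maximum inside the stack).
#' @export
axial_correlation_curve <- function(response, ref_plane = NULL,
                                    z_planes = NULL) {
  if (is.matrix(response)) dim(response) <- c(dim(response), 1L)
  d <- dim(response)
  if (d[3] < 2) stop("need at least 2 planes", call. = FALSE)
  cfg <- attr(response, "config")
  if (is.null(z_planes))
    z_planes <- if (!is.null(cfg)) cfg$z_planes else seq_len(d[3])
  if (is.null(ref_plane)) ref_plane <- (d[3] + 1L) %/% 2L
  ref <- response[, , ref_plane]
  ref <- ref - mean(ref)
  nref <- sqrt(sum(ref^2))
  if (nref == 0) stop("constant reference plane: correlation undefined",
                      call. = FALSE)
  rhat <- Conj(fft2(ref))
  peaks <- numeric(d[3])
  for (iz in seq_len(d[3])) {
    pl <- response[, , iz]
    pl <- pl - mean(pl)
    npl <- sqrt(sum(pl^2))
    if (npl == 0) stop("constant plane: correlation undefined", call. = FALSE)
    cc <- Re(ifft2(fft2(pl) * rhat))
    peaks[iz] <- max(cc) / (nref * npl)
  }
  peaks[ref_plane] <- 1  # self-correlation, exactly
  dz <- z_planes - z_planes[ref_plane]
  fwhm <- tryCatch(profile_fwhm(peaks, spacing = mean(diff(z_planes))),
                   error = function(e) NA_real_)
  structure(list(dz = dz, peak_value = peaks, fwhm = fwhm,
                 ref_plane = ref_plane),
            class = "correlation_curve")
}

#' Axial response profile of an in-focus point source
#'
#' Wiener-deconvolves a single-plane point-source scan image against every
#' plane of the response stack and records each plane's peak value: the
#' axial profile whose FWHM measures the axial resolution of plane-by-plane
#' demixing. Under saturated excitation this profile narrows.
#'
#' @param image A `scan_image` generated from a single in-focus point
#'   source.
#' @param response Response stack `c(ny, nx, nz)`.
#' @param params A [wiener_params()].
#' @return Numeric vector of per-plane peak values (one per z-plane).
#' @export
axial_response_profile <- function(image, response,
                                   params = wiener_params()) {
  if (is.matrix(response)) dim(response) <- c(dim(response), 1L)
  d <- dim(response)
  vapply(seq_len(d[3]), function(iz)
    max(wiener_plane(image, response[, , iz], params)), numeric(1))
}

#' Transverse spectral support of a response plane
#'
#' Largest radial spatial frequency at which the azimuthally averaged power
#' spectral density still exceeds `floor_fraction` times its DC-adjacent
#' value. Linear speckle intensity is band limited to `2 NA / lambda`;
#' saturation broadens the support, which is the spectral signature of
#' super-resolution.
#'
#' @param plane Numeric matrix.
#' @param pixel_size Transverse pixel size (nm).
#' @param floor_fraction Detection floor relative to the first off-DC
#'   radial bin, in (0, 1); default `1e-3`, reported alongside the value.
#' @return List with `support` (cycles/nm), `floor_fraction`, and the
#'   radial profile (`freq`, `psd`).
#' @export
spectral_support <- function(plane, pixel_size = 1, floor_fraction = 1e-3) {
  stopifnot(is.matrix(plane), floor_fraction > 0, floor_fraction < 1)
  ny <- nrow(plane); nx <- ncol(plane)
  psd <- Mod(fft2(plane - mean(plane)))^2
  fy <- fft_freq(ny, pixel_size); fx <- fft_freq(nx, pixel_size)
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  df <- 1 / (max(ny, nx) * pixel_size)
  bin <- round(fr / df)
  agg <- tapply(as.numeric(psd), as.integer(bin), mean)
  freq <- as.integer(names(agg)) * df
  ord <- order(freq)
  freq <- freq[ord]; agg <- as.numeric(agg)[ord]
  if (length(agg) < 2 || all(agg[-1] == 0))
    return(list(support = 0, floor_fraction = floor_fraction,
                freq = freq, psd = agg))
  ref <- agg[2]  # first off-DC bin
  above <- which(agg > floor_fraction * ref)
  above <- above[above > 1]
  support <- if (length(above) == 0) 0 else max(freq[above])
  list(support = support, floor_fraction = floor_fraction,
       freq = freq, psd = agg)
}

#' Peak-to-background SNR of a 3D reconstruction
#'
#' Compares a reconstruction against the exact ground truth of its
#' phantom: `peak` is the mean estimate over true source voxels,
#' `background_rms` the root-mean-square over voxels at least three
#' transverse grain lengths (in pixels) away from every source, and `snr`
#' their ratio. A perfect reconstruction has zero background; its SNR is
#' reported as the sentinel `Inf`.
#'
#' @param estimate An [object3d()] (e.g. a Wiener or FISTA estimate).
#' @param truth An [object3d()] phantom with at least one ground-truth
#'   source.
#' @param grain_px Transverse grain length in pixels (sets the source
#'   exclusion radius `3 * grain_px`).
#' @return List with `peak`, `background_rms`, `snr`.
#' @export
reconstruction_snr <- function(estimate, truth, grain_px = 2) {
  stopifnot(inherits(estimate, "object3d"), inherits(truth, "object3d"))
  gt <- truth$ground_truth
  if (is.null(gt) || nrow(gt) == 0)
    stop("truth carries no ground-truth sources", call. = FALSE)
  d <- dim(estimate$density)
  src <- cbind(round(gt$y), round(gt$x), round(gt$z))
  peak <- mean(estimate$density[src])
  # transverse distance to the nearest source, per (y, x); background
  # voxels are far from every source in its own plane's neighbourhood
  yy <- matrix(seq_len(d[1]), d[1], d[2])
  xx <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  min_d2 <- matrix(Inf, d[1], d[2])
  for (s in seq_len(nrow(src)))
    min_d2 <- pmin(min_d2, (yy - src[s, 1])^2 + (xx - src[s, 2])^2)
  far <- min_d2 >= (3 * grain_px)^2
  bg <- estimate$density[array(far, d)]
  background_rms <- sqrt(mean(bg^2))
  snr <- if (background_rms == 0) Inf else abs(peak) / background_rms
  list(peak = peak, background_rms = background_rms, snr = snr)
}

#' Compressed-sensing measurement budget check
#'
#' Sparse recovery from random projections needs on the order of
#' `K log(total voxels)` independent measurements; this predicate checks
#' `M >= constant * K * log(Nx Ny Nz)` for a calibration constant supplied
#' by the user (the package's phase-transition test reports a fitted
#' value).
#'
#' @param K Sparsity (number of nonzero voxels), >= 0.
#' @param grid_shape Integer `c(ny, nx, nz)`.
#' @param M Number of measurements.
#' @param constant Calibration constant.
#' @return TRUE when the budget is satisfied.
#' @export
sparsity_budget <- function(K, grid_shape, M, constant = 1) {
  stopifnot(K >= 0, M > 0, constant > 0, all(grid_shape > 0))
  M >= constant * K * log(prod(as.numeric(grid_shape)))
}
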