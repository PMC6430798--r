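#' Optical configuration for speckle simulation
#'
#' Bundles the optical parameters (wavelength, numerical aperture, medium
#' index) with the discretisation (transverse pixel size, grid shape, axial
#' plane positions) used by every simulation and reconstruction routine.
#'
#' All lengths are in nanometres. The transverse sampling must satisfy the
#' intensity Nyquist condition `pixel_size_xy <= wavelength / (4 * na)`:
#' speckle intensity is band limited to `2 NA / lambda` cycles per nm, so a
#' coarser grid would alias the pattern. Axial positions are relative to the
#' reference (focal) plane and must be strictly increasing.
#'
#' @param wavelength Vacuum wavelength (nm), positive.
#' @param na Numerical aperture, in (0, 1.7]; must be smaller than
#'   `medium_index` so that every pupil plane wave propagates.
#' @param medium_index Refractive index of the immersion/sample medium
#'   (>= 1).
#' @param pixel_size_xy Transverse sampling step (nm).
#' @param grid_shape Integer vector `c(ny, nx)` of transverse grid sizes.
#' @param z_planes Numeric vector of axial plane positions (nm), strictly
#'   increasing; a single plane is allowed.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(wavelength = 532, na = 0.77, medium_index = 1.515,
#'                       pixel_size_xy = 100, grid_shape = c(128, 128),
#'                       z_planes = seq(-2000, 2000, by = 500))
#' grain_sizes(cfg)
#' @export
optical_config <- function(wavelength, na, medium_index = 1.0,
                           pixel_size_xy, grid_shape, z_planes = 0) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1, wavelength > 0)
  if (!(na > 0 && na <= 1.7))
    stop("`na` must lie in (0, 1.7]", call. = FALSE)
  if (!(medium_index >= 1))
    stop("`medium_index` must be >= 1", call. = FALSE)
  if (!(na < medium_index))
    stop("`na` must be smaller than `medium_index` (no evanescent pupil components)",
         call. = FALSE)
  if (pixel_size_xy <= 0)
    stop("`pixel_size_xy` must be positive", call. = FALSE)
  nyq <- wavelength / (4 * na)
  if (pixel_size_xy > nyq + 1e-9)
    stop(sprintf(
      "pixel_size_xy = %g nm violates the intensity Nyquist limit lambda/(4 NA) = %.3f nm",
      pixel_size_xy, nyq), call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(grid_shape < 2))
    stop("`grid_shape` must be two integers >= 2 (ny, nx)", call. = FALSE)
  z_planes <- as.numeric(z_planes)
  if (length(z_planes) < 1 || is.unsorted(z_planes, strictly = TRUE))
    stop("`z_planes` must be strictly increasing", call. = FALSE)
  structure(
    list(wavelength = wavelength, na = na, medium_index = medium_index,
         pixel_size_xy = pixel_size_xy, grid_shape = grid_shape,
         z_planes = z_planes),
    class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  lambda = %g nm, NA = %g, n = %g\n",
              x$wavelength, x$na, x$medium_index))
  cat(sprintf("  grid %d x %d, pixel %g nm, %d z-plane(s) [%g..%g nm]\n",
              x$grid_shape[1], x$grid_shape[2], x$pixel_size_xy,
              length(x$z_planes), min(x$z_planes), max(x$z_planes)))
  invisible(x)
}

#' Characteristic speckle grain sizes
#'
#' Transverse and axial speckle grain dimensions set by diffraction:
#' the transverse grain is `lambda / (2 NA)` and the axial grain is
#' `2 n lambda / NA^2`. Transverse planes separated by more than the axial
#' grain are statistically orthogonal, which is what permits plane-by-plane
#' demixing of a single 2D scan.
#'
#' @param config An [optical_config()].
#' @return List with elements `transverse` and `axial`, both in nm.
#' @export
grain_sizes <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  list(transverse = config$wavelength / (2 * config$na),
       axial = 2 * config$medium_index * config$wavelength / config$na^2)
}

#' Index of the reference (in-focus) plane
#'
#' The plane whose axial position is closest to z = 0; intensity stacks are
#' normalised to unit mean over this plane.
#' @param config An [optical_config()].
#' @return Integer plane index.
#' @export
reference_plane <- function(config) {
  which.min(abs(config$z_planes))
}

## --- Fourier grid helpers (internal) ------------------------------------

# DFT sample frequencies in cycles per unit, unshifted (DC first),
# matching the ordering of R's fft().
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# Angular spatial-frequency radius |k_perp| (rad/nm) on the (ny, nx) grid,
# unshifted ordering.
k_perp_grid <- function(config) {
  ny <- config$grid_shape[1]; nx <- config$grid_shape[2]
  ky <- 2 * pi * fft_freq(ny, config$pixel_size_xy)
  kx <- 2 * pi * fft_freq(nx, config$pixel_size_xy)
  sqrt(outer(ky^2, kx^2, `+`))
}

# Shift DC to the array centre (and back). For even n the two are inverse
# to each other along that axis; for odd n fft_unshift undoes fft_shift.
fft_shift <- function(x) {
  d <- dim(x); if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    h <- ceiling(n / 2)
    c(seq.int(h + 1L, n), seq_len(h))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

fft_unshift <- function(x) {
  d <- dim(x); if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    h <- floor(n / 2)
    c(seq.int(h + 1L, n), seq_len(h))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)
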