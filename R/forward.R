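#' 2D scan image container
#'
#' The single 2D raster-scan fluorescence image `b`: at scan offset `r0`
#' the detected signal is the object sampled by the shifted excitation,
#' summed over all planes. The scan step equals the transverse pixel size
#' of the simulated response.
#'
#' @param values Numeric matrix of scan values.
#' @param scan_step Scan step (nm).
#' @param provenance Optional list recording object/response/noise/seed.
#' @return An object of class `scan_image`.
#' @export
scan_image_new <- function(values, scan_step = NA_real_, provenance = list()) {
  stopifnot(is.matrix(values))
  structure(list(values = values, scan_step = scan_step,
                 provenance = provenance),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("<scan_image> %d x %d, step %g nm, mean %.4g\n",
              nrow(x$values), ncol(x$values), x$scan_step, mean(x$values)))
  invisible(x)
}

# Per-plane FFTs of a response stack (ny, nx, nz) -> complex array.
response_fft <- function(response) {
  d <- dim(response)
  out <- array(0 + 0i, d)
  for (iz in seq_len(d[3])) out[, , iz] <- fft2(response[, , iz])
  out
}

# Shared forward operator core: circular per-plane cross-correlation of
# the object with the response, summed over z. Single source of truth for
# scan_image() and the FISTA forward operator.
forward_operator <- function(density, rfft) {
  d <- dim(density)
  acc <- matrix(0 + 0i, d[1], d[2])
  for (iz in seq_len(d[3])) {
    acc <- acc + fft2(density[, , iz]) * Conj(rfft[, , iz])
  }
  Re(ifft2(acc))
}

# Adjoint of forward_operator: per-plane circular convolution of the scan
# residual with the response, stacked over z.
adjoint_operator <- function(r, rfft) {
  d <- dim(rfft)
  out <- array(0, d)
  rhat <- fft2(r)
  for (iz in seq_len(d[3])) out[, , iz] <- Re(ifft2(rhat * rfft[, , iz]))
  out
}

#' Single 2D scan image of a 3D object
#'
#' Forms `b(r0) = sum_z sum_r O_z(r) F_z(r - r0)`: each object plane is
#' circularly cross-correlated with its response plane and the plane
#' contributions are summed, exactly the measurement a 2D raster scan of a
#' 3D sample under a 3D speckle excitation produces. Computed spectrally
#' with periodic boundaries, consistent with the statistically homogeneous
#' speckle model.
#'
#' @param object An [object3d()].
#' @param response Response stack, numeric array `c(ny, nx, nz)` matching
#'   the object's grid (e.g. from [fluorescence_response()]).
#' @return A `scan_image`.
#' @export
scan_image <- function(object, response) {
  stopifnot(inherits(object, "object3d"))
  if (is.matrix(response)) dim(response) <- c(dim(response), 1L)
  if (!all(dim(object$density) == dim(response)))
    stop("object and response grids differ", call. = FALSE)
  b <- forward_operator(object$density, response_fft(response))
  cfg <- attr(response, "config")
  scan_image_new(b, scan_step = if (!is.null(cfg)) cfg$pixel_size_xy else
    object$voxel_size[2],
    provenance = list(type = "scan"))
}

#' Point-scanning (confocal-style) image stack
#'
#' For comparison with speckle scanning: convolves each object plane with
#' the diffraction-limited focal intensity of a uniformly filled NA disk
#' (Airy-type pattern), one output image per z-plane. Uses the same
#' periodic spectral convention as [scan_image()].
#'
#' @param object An [object3d()].
#' @param config An [optical_config()] whose grid matches the object.
#' @return Numeric array `c(ny, nx, nz)` of per-plane images.
#' @export
point_scan_image <- function(object, config) {
  stopifnot(inherits(object, "object3d"), inherits(config, "optical_config"))
  d <- dim(object$density)
  stopifnot(all(d[1:2] == config$grid_shape))
  psf <- airy_intensity(config)
  psf_hat <- fft2(psf / sum(psf))
  out <- array(0, d)
  for (iz in seq_len(d[3]))
    out[, , iz] <- Re(ifft2(fft2(object$density[, , iz]) * psf_hat))
  out
}

# Diffraction-limited focal intensity |IFT(uniform NA disk)|^2, centred at
# the origin pixel (unshifted ordering).
airy_intensity <- function(config) {
  k_max <- config$na * 2 * pi / config$wavelength
  disk <- (k_perp_grid(config) <= k_max) + 0
  Mod(ifft2(disk))^2
}

#' Poisson shot noise and constant background
#'
#' Scales the image so its mean maps to `photons_at_mean` expected counts,
#' adds a constant background, and draws independent Poisson counts per
#' pixel. The returned image is in counts (not rescaled back), as a
#' photon-counting detector would deliver it.
#'
#' @param image A `scan_image`.
#' @param photons_at_mean Expected photon count at the image mean (> 0).
#' @param background Constant expected background counts per pixel (>= 0).
#' @param seed Integer seed.
#' @return A `scan_image` of Poisson counts.
#' @export
apply_noise <- function(image, photons_at_mean, background = 0, seed = 1) {
  stopifnot(inherits(image, "scan_image"), photons_at_mean > 0,
            background >= 0)
  v <- image$values
  m <- mean(v)
  lam <- if (m > 0) v * (photons_at_mean / m) else v * 0
  lam <- lam + background
  counts <- withr::with_seed(as.integer(seed), {
    matrix(stats::rpois(length(lam), lambda = pmax(lam, 0)),
           nrow(lam), ncol(lam))
  })
  scan_image_new(counts * 1.0, image$scan_step,
                 c(image$provenance,
                   list(noise = list(photons_at_mean = photons_at_mean,
                                     background = background, seed = seed))))
}
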