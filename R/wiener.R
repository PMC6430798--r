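#' Wiener deconvolution parameters
#'
#' A single flat (white) spectral noise density regularises the spectral
#' division, the one tunable knob of plane-by-plane Wiener deconvolution.
#' When `noise_psd` is `NULL` each deconvolved plane uses the reproducible
#' relative default `rel_floor * max_{k != 0} |F_hat_z(k)|^2`, referenced
#' to that plane's strongest structural (off-DC) spectral component: the
#' DC bin only encodes the mean response level, which under saturation
#' dwarfs every structural frequency and would otherwise set a wildly
#' over-regularised scale. `noise_psd = 0` (the unregularised inverse
#' filter) is only permitted with `inverse_filter = TRUE`.
#'
#' In an experiment `rel_floor` plays the role of the visually tuned noise
#' parameter: raise it for noisy images, lower it toward the whitening
#' limit for clean ones.
#'
#' @param noise_psd Absolute flat noise power spectral density (>= 0), or
#'   `NULL` to use the relative default.
#' @param rel_floor Relative noise floor used when `noise_psd` is `NULL`.
#' @param inverse_filter Explicitly allow `noise_psd = 0`.
#' @return An object of class `wiener_params`.
#' @export
wiener_params <- function(noise_psd = NULL, rel_floor = 1e-3,
                          inverse_filter = FALSE) {
  if (!is.null(noise_psd)) {
    stopifnot(is.numeric(noise_psd), length(noise_psd) == 1, noise_psd >= 0)
    if (noise_psd == 0 && !inverse_filter)
      stop("noise_psd = 0 requires inverse_filter = TRUE", call. = FALSE)
  }
  stopifnot(rel_floor > 0)
  structure(list(noise_psd = noise_psd, rel_floor = rel_floor,
                 inverse_filter = inverse_filter),
            class = "wiener_params")
}

# Wiener spectral filter for one response plane under the correlation
# forward convention b_hat = O_hat * Conj(F_hat): the estimate spectrum is
# B_hat * F_hat / (|F_hat|^2 + noise_psd), which puts a point source back
# at its true position.
wiener_plane_core <- function(bhat, fhat, params) {
  p2 <- Mod(fhat)^2
  npsd <- params$noise_psd
  if (is.null(npsd)) npsd <- params$rel_floor * max(p2[-1])  # off-DC max
  Re(ifft2(bhat * fhat / (p2 + npsd)))
}

#' Wiener deconvolution of a scan image against one response plane
#'
#' Spectral division of the 2D scan image by one plane of the speckle
#' response, regularised by a flat noise density. Because speckle planes at
#' different depths are statistically orthogonal, deconvolving against the
#' matched plane produces a sharp estimate of that plane's sources while
#' mismatched planes yield only low-level background.
#'
#' @param image A `scan_image`.
#' @param response_plane Numeric matrix, one plane of the response stack.
#' @param params A [wiener_params()].
#' @return Numeric matrix, the estimated object plane (unclipped).
#' @export
wiener_plane <- function(image, response_plane, params = wiener_params()) {
  stopifnot(inherits(image, "scan_image"), is.matrix(response_plane))
  if (!all(dim(image$values) == dim(response_plane)))
    stop("image and response grids differ", call. = FALSE)
  if (all(response_plane == 0))
    stop("response plane is identically zero", call. = FALSE)
  wiener_plane_core(fft2(image$values), fft2(response_plane), params)
}

#' Plane-by-plane Wiener reconstruction of a 3D object
#'
#' Applies [wiener_plane()] to every plane of the response stack and stacks
#' the results: the projection of the single 2D scan on each transverse
#' speckle plane, i.e. a full 3D reconstruction with no cross-plane
#' coupling. Output is not clipped at zero unless requested, so
#' reconstruction noise stays visible.
#'
#' @param image A `scan_image`.
#' @param response Response stack `c(ny, nx, nz)`.
#' @param params A [wiener_params()].
#' @param clip Set negative values to zero.
#' @return An [object3d()] estimate (possibly with negative values when
#'   `clip = FALSE`).
#' @export
wiener_stack <- function(image, response, params = wiener_params(),
                         clip = FALSE) {
  if (is.matrix(response)) dim(response) <- c(dim(response), 1L)
  d <- dim(response)
  stopifnot(all(dim(image$values) == d[1:2]))
  est <- array(0, d)
  for (iz in seq_len(d[3]))
    est[, , iz] <- wiener_plane(image, response[, , iz], params)
  if (clip) est[est < 0] <- 0
  object3d(est, validate = FALSE)
}

#' Cross-correlation projection of a scan image on each response plane
#'
#' Plain matched filtering: the image is cross-correlated with every
#' response plane (the infinite-noise limit of Wiener deconvolution),
#' normalised by each plane's energy. Peaks are wider than Wiener's but the
#' operation is linear and parameter free.
#'
#' @param image A `scan_image`.
#' @param response Response stack `c(ny, nx, nz)`.
#' @return An [object3d()] estimate.
#' @export
crosscorr_project <- function(image, response) {
  if (is.matrix(response)) dim(response) <- c(dim(response), 1L)
  d <- dim(response)
  stopifnot(all(dim(image$values) == d[1:2]))
  bhat <- fft2(image$values)
  est <- array(0, d)
  for (iz in seq_len(d[3])) {
    f <- response[, , iz]
    est[, , iz] <- Re(ifft2(bhat * fft2(f))) / sum(f^2)
  }
  object3d(est, validate = FALSE)
}
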