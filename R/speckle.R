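#' Random pupil field for fully developed speckle
#'
#' Builds the complex pupil function whose focal field is a fully developed
#' speckle pattern: unit amplitude inside the numerical-aperture disk
#' `|k_perp| <= iris_fraction * NA * 2 pi / lambda`, with independent phases
#' uniform on `[0, 2 pi)`, and exactly zero outside. The iris fraction
#' models a physical iris stopping down the effective NA.
#'
#' The returned pupil array follows the package's display convention with
#' DC at the array centre; propagation routines re-order it internally.
#'
#' @param config An [optical_config()].
#' @param seed Integer seed; the pupil is bitwise reproducible for a fixed
#'   seed.
#' @param iris_fraction Scale factor in (0, 1] applied to the NA disk
#'   radius.
#' @return An object of class `pupil_field` with elements `field` (complex
#'   ny x nx matrix, DC-centred), `config`, `seed`, `iris_fraction`.
#' @export
build_pupil <- function(config, seed, iris_fraction = 1.0) {
  stopifnot(inherits(config, "optical_config"))
  if (!(iris_fraction > 0 && iris_fraction <= 1))
    stop("`iris_fraction` must lie in (0, 1]", call. = FALSE)
  k_max <- iris_fraction * config$na * 2 * pi / config$wavelength
  kp <- k_perp_grid(config)
  disk <- kp <= k_max
  # require at least 8 frequency samples across the disk in each direction
  dky <- 2 * pi / (config$grid_shape[1] * config$pixel_size_xy)
  dkx <- 2 * pi / (config$grid_shape[2] * config$pixel_size_xy)
  if (2 * k_max / dky < 8 || 2 * k_max / dkx < 8)
    stop("grid too small: fewer than 8 frequency samples across the NA disk",
         call. = FALSE)
  phases <- withr::with_seed(as.integer(seed),
    stats::runif(sum(disk), min = 0, max = 2 * pi))
  field <- matrix(0 + 0i, config$grid_shape[1], config$grid_shape[2])
  field[disk] <- exp(1i * phases)
  structure(
    list(field = fft_shift(field), config = config, seed = as.integer(seed),
         iris_fraction = iris_fraction),
    class = "pupil_field")
}

#' Propagate a pupil field to a stack of axial planes
#'
#' Angular-spectrum propagation with the full non-paraxial axial wavenumber
#' `k_z = sqrt((n 2 pi / lambda)^2 - |k_perp|^2)`: each plane is the inverse
#' Fourier transform of the pupil multiplied by `exp(i k_z z)`. The plane at
#' z = 0 therefore equals the direct inverse transform of the pupil, and the
#' propagation is unitary (per-plane energy equals pupil energy).
#'
#' The NA < n invariant of [optical_config()] guarantees no evanescent
#' components inside the pupil support, so `k_z` is always real.
#'
#' @param pupil A [build_pupil()] result.
#' @param z_planes Axial positions (nm), strictly increasing; defaults to
#'   the configuration's planes.
#' @param polarization `"scalar"` (default) or `"circular_vectorial"`. The
#'   vectorial mode adds an axial field component `Ez ~ sin(theta)
#'   exp(i phi_k)` with `sqrt(cos(theta))` apodization for circularly
#'   polarized input, which partially fills the intensity zeros of the
#'   scalar model.
#' @return An object of class `speckle_volume`: `field` is a complex array
#'   `c(ny, nx, nz)` (scalar) or `c(ny, nx, nz, 3)` (vectorial), `config`
#'   carries the realised `z_planes`.
#' @export
propagate <- function(pupil, z_planes = NULL,
                      polarization = c("scalar", "circular_vectorial")) {
  stopifnot(inherits(pupil, "pupil_field"))
  polarization <- match.arg(polarization)
  config <- pupil$config
  if (is.null(z_planes)) z_planes <- config$z_planes
  z_planes <- as.numeric(z_planes)
  if (is.unsorted(z_planes, strictly = TRUE) && length(z_planes) > 1)
    stop("`z_planes` must be strictly increasing", call. = FALSE)
  config$z_planes <- z_planes
  ny <- config$grid_shape[1]; nx <- config$grid_shape[2]
  nz <- length(z_planes)

  p0 <- fft_unshift(pupil$field)           # DC-first ordering for fft()
  kp <- k_perp_grid(config)
  nk0 <- config$medium_index * 2 * pi / config$wavelength
  supp <- Mod(p0) > 0
  stopifnot(all(kp[supp] < nk0))           # NA < n: never evanescent
  kz <- sqrt(pmax(nk0^2 - kp^2, 0))

  components <- list(p0)
  if (polarization == "circular_vectorial") {
    sin_t <- pmin(kp / nk0, 1)
    cos_t <- kz / nk0
    ky <- 2 * pi * fft_freq(ny, config$pixel_size_xy)
    kx <- 2 * pi * fft_freq(nx, config$pixel_size_xy)
    phi_k <- atan2(outer(ky, rep(1, nx)), outer(rep(1, ny), kx))
    # circular input (ex + i ey)/sqrt(2); axial component from the
    # high-NA bending of rays, apodized by sqrt(cos theta)
    components <- list(p0 / sqrt(2), 1i * p0 / sqrt(2),
                       p0 * sin_t * exp(1i * phi_k) * sqrt(cos_t))
  }

  ncomp <- length(components)
  field <- array(0 + 0i, c(ny, nx, nz, ncomp))
  for (iz in seq_len(nz)) {
    prop <- exp(1i * kz * z_planes[iz])
    for (ic in seq_len(ncomp))
      field[, , iz, ic] <- ifft2(components[[ic]] * prop)
  }
  if (ncomp == 1) dim(field) <- c(ny, nx, nz)
  structure(
    list(field = field, config = config, polarization = polarization,
         seed = pupil$seed),
    class = "speckle_volume")
}

#' Intensity stack of a speckle volume
#'
#' Squared modulus of the field (summed over polarization components in
#' vectorial mode), normalised so the mean over the reference plane (the
#' z-plane closest to 0) equals 1. This normalisation plane is the one the
#' saturation parameter refers to.
#'
#' @param volume A [propagate()] result.
#' @return Nonnegative numeric array `c(ny, nx, nz)`, attribute `config`.
#' @export
intensity <- function(volume) {
  stopifnot(inherits(volume, "speckle_volume"))
  f <- volume$field
  if (length(dim(f)) == 4) {
    I <- apply(Mod(f)^2, c(1, 2, 3), sum)
  } else {
    I <- Mod(f)^2
  }
  ref <- reference_plane(volume$config)
  m <- mean(I[, , ref])
  if (!(is.finite(m) && m > 0))
    stop("reference plane has non-positive mean intensity", call. = FALSE)
  out <- I / m
  attr(out, "config") <- volume$config
  out
}

#' First-order speckle statistics of a plane
#'
#' Fully developed speckle has an exponential intensity probability density
#' `rho(I) = exp(-I/<I>)/<I>` and unit contrast (std/mean). This check
#' returns the empirical contrast and the sup-norm (Kolmogorov) distance
#' between the empirical intensity CDF and the exponential CDF with the
#' plane's own mean.
#'
#' The test is meaningful only when the plane contains many statistically
#' independent grains; a heuristic grain count is `area / (lambda/(2 NA))^2`.
#'
#' @param plane Nonnegative numeric matrix.
#' @return List with `contrast` and `pdf_distance`.
#' @export
check_rayleigh <- function(plane) {
  stopifnot(is.numeric(plane))
  v <- as.numeric(plane)
  if (any(v < 0)) stop("negative intensities", call. = FALSE)
  m <- mean(v)
  if (m == 0) stop("degenerate input: all-zero plane", call. = FALSE)
  contrast <- stats::sd(v) / m
  # exact KS sup-distance against Exp(mean = m)
  x <- sort(v)
  n <- length(x)
  cdf <- stats::pexp(x, rate = 1 / m)
  d <- max(pmax(abs(seq_len(n) / n - cdf), abs(cdf - (seq_len(n) - 1) / n)))
  list(contrast = contrast, pdf_distance = d)
}
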