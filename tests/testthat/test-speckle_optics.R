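test_that("optical_config enforces sampling and physical invariants", {
  expect_error(optical_config(532, 0.77, 1.515, 200, c(64, 64), 0),
               "Nyquist")
  expect_error(optical_config(532, 1.2, 1.0, 100, c(64, 64), 0),
               "smaller than")
  expect_error(optical_config(532, 0.77, 1.515, 100, c(64, 64),
                              c(0, -100)), "increasing")
  cfg <- std_cfg(64)
  expect_s3_class(cfg, "optical_config")
  expect_equal(reference_plane(cfg), 13L)  # z = 0 of 25 planes
})

test_that("grain sizes follow the diffraction formulas", {
  cfg <- std_cfg(64)
  g <- grain_sizes(cfg)
  expect_equal(g$transverse, 532 / (2 * 0.77), tolerance = 1e-12)
  expect_equal(g$transverse, 345.45, tolerance = 1e-4)
  expect_equal(g$axial, 2 * 1.515 * 532 / 0.77^2, tolerance = 1e-12)
  expect_equal(g$axial, 2718.77, tolerance = 1e-5)
  # 1/NA^2: halving NA quadruples the axial grain
  cfg2 <- optical_config(532, 0.77 / 2, 1.515, 100, c(64, 64), 0)
  expect_equal(grain_sizes(cfg2)$axial, 4 * g$axial, tolerance = 1e-12)
})

test_that("pupil is deterministic, iris-scaled, and disk-shaped", {
  cfg <- std_cfg(128)
  p1 <- build_pupil(cfg, seed = 7)
  p2 <- build_pupil(cfg, seed = 7)
  expect_identical(p1$field, p2$field)  # bitwise
  expect_false(identical(p1$field, build_pupil(cfg, seed = 8)$field))

  # support radius halves with iris_fraction = 0.5 (within one bin)
  radius_bins <- function(p) {
    nz_idx <- which(Mod(p$field) > 0, arr.ind = TRUE)
    c0 <- floor(dim(p$field) / 2) + 1
    max(sqrt((nz_idx[, 1] - c0[1])^2 + (nz_idx[, 2] - c0[2])^2))
  }
  r_full <- radius_bins(p1)
  r_half <- radius_bins(build_pupil(cfg, seed = 7, iris_fraction = 0.5))
  expect_lt(abs(r_half - r_full / 2), 1)

  # occupied fraction matches the analytic disk area within 5%
  k_max <- 0.77 * 2 * pi / 532
  dk <- 2 * pi / (128 * 100)
  r <- k_max / dk
  frac <- mean(Mod(p1$field) > 0)
  expect_lt(abs(frac - pi * r^2 / 128^2) / (pi * r^2 / 128^2), 0.05)

  # amplitude is uniform on the disk
  expect_equal(unique(round(Mod(p1$field[Mod(p1$field) > 0]), 12)), 1)

  expect_error(build_pupil(std_cfg(16), seed = 1, iris_fraction = 0.1),
               "8 frequency samples")
})

test_that("angular-spectrum propagation is unitary and anchored at z = 0", {
  cfg <- std_cfg(64, z = c(-800, 0, 800))
  pupil <- build_pupil(cfg, seed = 3)
  vol <- propagate(pupil)
  # z = 0 plane equals the direct inverse transform of the pupil
  direct <- stats::fft(specklescope:::fft_unshift(pupil$field),
                       inverse = TRUE) / (64 * 64)
  expect_equal(vol$field[, , 2], direct, tolerance = 1e-12)

  # propagate to +z then back to -z: unitarity recovers the z = 0 plane
  kp <- specklescope:::k_perp_grid(cfg)
  nk0 <- 1.515 * 2 * pi / 532
  kz <- sqrt(pmax(nk0^2 - kp^2, 0))
  fwd <- stats::fft(vol$field[, , 3])
  back <- stats::fft(fwd * exp(-1i * kz * 800), inverse = TRUE) / (64 * 64)
  expect_lt(max(Mod(back - vol$field[, , 2])) / max(Mod(vol$field[, , 2])),
            1e-9)

  # Parseval: per-plane energy equals pupil energy within 1e-6 relative
  e_pupil <- sum(Mod(pupil$field)^2) / (64 * 64)
  for (iz in 1:3)
    expect_equal(sum(Mod(vol$field[, , iz])^2), e_pupil, tolerance = 1e-6)

  # full volume bitwise reproducible from the seed
  vol2 <- propagate(build_pupil(cfg, seed = 3))
  expect_identical(vol$field, vol2$field)
})

test_that("transverse speckle grain size matches lambda/(2 NA)", {
  # Monte-Carlo autocorrelation FWHM over 10 seeds, fine 50 nm sampling
  fwhms <- vapply(1:10, function(seed) {
    I <- sim_intensity(seed, n = 256, pixel = 50, z = 0)[, , 1]
    ac <- Re(stats::fft(Mod(stats::fft(I - mean(I)))^2,
                        inverse = TRUE)) / length(I)
    ac <- specklescope:::fft_shift(ac)
    profile_fwhm(ac[129, ], spacing = 50)
  }, numeric(1))
  expect_lt(abs(median(fwhms) - 345.45) / 345.45, 0.15)
})

test_that("plane-wave (single-point) pupil gives unit constant intensity", {
  cfg <- std_cfg(64, z = c(-500, 0, 500))
  pupil <- build_pupil(cfg, seed = 1)
  pupil$field[] <- 0
  pupil$field[33, 33] <- 1  # DC bin only: a plane wave
  I <- intensity(propagate(pupil))
  expect_equal(max(abs(I - 1)), 0, tolerance = 1e-9)
})

test_that("intensity is nonnegative and normalised on the reference plane", {
  for (seed in 1:3) {
    I <- sim_intensity(seed, n = 128, z = c(-1000, 0, 1000))
    expect_gte(min(I), 0)
    expect_equal(mean(I[, , 2]), 1, tolerance = 1e-12)
  }
})

test_that("vectorial mode fills scalar intensity zeros", {
  cfg <- std_cfg(128, z = 0)
  for (seed in 1:3) {
    pupil <- build_pupil(cfg, seed = seed)
    I_s <- intensity(propagate(pupil))
    I_v <- intensity(propagate(pupil, polarization = "circular_vectorial"))
    expect_gte(min(I_v), min(I_s))
  }
})

test_that("fully developed speckle has exponential intensity statistics", {
  # contrast ~ 1 and small CDF distance, 10-seed check at >= 1e5 samples
  stats <- vapply(1:10, function(seed) {
    pl <- sim_intensity(seed, n = 512, z = 0)[, , 1]
    s <- check_rayleigh(pl)
    c(s$contrast, s$pdf_distance)
  }, numeric(2))
  expect_true(all(stats[1, ] > 0.9 & stats[1, ] < 1.1))
  expect_lt(median(stats[2, ]), 0.02)
})

test_that("check_rayleigh handles reference and degenerate inputs", {
  x <- withr::with_seed(1, matrix(stats::rexp(1e5), 250))
  s <- check_rayleigh(x)
  expect_lt(abs(s$contrast - 1), 0.05)
  expect_lt(s$pdf_distance, 0.01)
  expect_equal(check_rayleigh(matrix(3, 50, 50))$contrast, 0)
  expect_error(check_rayleigh(matrix(0, 50, 50)), "all-zero")
})

test_that("axial decorrelation length is consistent with 2 n lambda / NA^2", {
  fwhms <- vapply(1:10, function(seed) {
    I <- sim_intensity(seed, n = 128)
    axial_correlation_curve(fluorescence_response(I, 0))$fwhm
  }, numeric(1))
  g_ax <- grain_sizes(std_cfg(128))$axial
  expect_lt(abs(median(fwhms) - g_ax) / g_ax, 0.3)
})
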