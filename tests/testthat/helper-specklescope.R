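# Shared fixtures: every dataset is generated in code at test time.

std_cfg <- function(n = 128, pixel = 100, z = seq(-3000, 3000, by = 250)) {
  optical_config(wavelength = 532, na = 0.77, medium_index = 1.515,
                 pixel_size_xy = pixel, grid_shape = c(n, n), z_planes = z)
}

sim_intensity <- function(seed, n = 128, pixel = 100,
                          z = seq(-3000, 3000, by = 250)) {
  intensity(propagate(build_pupil(std_cfg(n, pixel, z), seed = seed)))
}

# A phantom of point sources confined to one plane of an nz-plane stack,
# with ground truth in stack coordinates.
single_plane_sparse <- function(n, nz, z_index, K, seed, min_sep_px = 12) {
  ph1 <- random_sparse(c(n, n, 1), K = K, seed = seed,
                       min_separation = min_sep_px,
                       voxel_size = c(1, 1, 1))
  dens <- array(0, c(n, n, nz))
  dens[, , z_index] <- ph1$density
  gt <- ph1$ground_truth
  gt$z <- z_index
  object3d(dens, ground_truth = gt)
}

# Standard sparsity weight for recovery experiments: a fixed 1% of the
# null threshold of the demeaned system (the largest lambda with a
# nonzero solution), the same rule the acceptance script applies.
lambda_for <- function(img, resp, frac = 0.01) {
  v <- if (inherits(img, "scan_image")) img$values else img
  resp_d <- resp
  for (iz in seq_len(dim(resp)[3]))
    resp_d[, , iz] <- resp_d[, , iz] - mean(resp_d[, , iz])
  frac * 2 * max(abs(adjoint_At(v - mean(v), resp_d)))
}

# Axial-narrowing simulations shared by the acceptance tests: for each
# seed, the Wiener axial response FWHM (linear and <s> = 1.4) and the
# axial correlation-curve FWHM (linear and <s> = 3.7), at the full
# 256 x 256 x 25-plane scale. Cached so the two criteria that consume it
# pay for the simulation once.
.sim_cache <- new.env(parent = emptyenv())

axial_narrowing_sims <- function(n_seeds = 10, n = 256) {
  key <- sprintf("axial_%d_%d", n_seeds, n)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  z <- seq(-3000, 3000, by = 250)
  wp <- wiener_params(rel_floor = 1e-7)  # whitening limit: noiseless data
  out <- do.call(rbind, lapply(seq_len(n_seeds), function(seed) {
    I <- sim_intensity(seed, n = n, z = z)
    nz <- dim(I)[3]
    ref <- (nz + 1L) %/% 2L
    ph <- beads(c(n, n, nz), matrix(c(n / 2, n / 2, ref), 1))
    resp_lin <- fluorescence_response(I, 0)
    resp_14 <- fluorescence_response(I, 1.4)
    prof_lin <- axial_response_profile(scan_image(ph, resp_lin), resp_lin, wp)
    prof_14 <- axial_response_profile(scan_image(ph, resp_14), resp_14, wp)
    corr_lin <- axial_correlation_curve(resp_lin)$fwhm
    corr_37 <- axial_correlation_curve(fluorescence_response(I, 3.7))$fwhm
    data.frame(seed = seed,
               wiener_fwhm_lin = profile_fwhm(prof_lin, 250),
               wiener_fwhm_s14 = profile_fwhm(prof_14, 250),
               corr_fwhm_lin = corr_lin,
               corr_fwhm_s37 = corr_37)
  }))
  .sim_cache[[key]] <- out
  out
}
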