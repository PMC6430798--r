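test_that("soft thresholding implements the l1 proximal map", {
  v <- c(-3, -0.5, 0, 0.2, 2)
  expect_equal(soft_threshold(v, 0), v)
  expect_equal(soft_threshold(v, 10), rep(0, 5))
  expect_equal(soft_threshold(v, 0.5), c(-2.5, 0, 0, 0, 1.5))
  expect_equal(soft_threshold(v, 0.5, nonneg = TRUE), c(0, 0, 0, 0, 1.5))
})

test_that("forward and adjoint operators satisfy the dot-product identity", {
  for (case in list(c(8, 8, 1), c(16, 12, 3), c(10, 10, 5))) {
    resp <- withr::with_seed(sum(case), array(stats::rexp(prod(case)), case))
    x <- withr::with_seed(1 + sum(case), array(stats::rnorm(prod(case)), case))
    r <- withr::with_seed(2 + sum(case),
                          matrix(stats::rnorm(prod(case[1:2])), case[1]))
    lhs <- sum(forward_A(x, resp) * r)
    rhs <- sum(x * adjoint_At(r, resp))
    expect_lt(abs(lhs - rhs) / max(abs(lhs), 1e-300), 1e-9)
  }
  # A^T of a delta image returns the response stack in object coordinates
  d <- c(8, 8, 2)
  resp <- withr::with_seed(3, array(stats::rexp(prod(d)), d))
  delta <- matrix(0, 8, 8); delta[1, 1] <- 1
  at <- adjoint_At(delta, resp)
  expect_equal(at, resp, tolerance = 1e-12)
  # linearity of the adjoint
  r1 <- withr::with_seed(4, matrix(stats::rnorm(64), 8))
  r2 <- withr::with_seed(5, matrix(stats::rnorm(64), 8))
  expect_equal(adjoint_At(r1 + 2 * r2, resp),
               adjoint_At(r1, resp) + 2 * adjoint_At(r2, resp),
               tolerance = 1e-12)
})

test_that("forward_A shares the scan-image code path", {
  d <- c(16, 16, 3)
  resp <- withr::with_seed(6, array(stats::rexp(prod(d)), d))
  dens <- withr::with_seed(7, array(stats::runif(prod(d)), d))
  expect_identical(forward_A(dens, resp),
                   scan_image(object3d(dens), resp)$values)
  expect_true(all(forward_A(array(0, d), resp) == 0))
})

test_that("Lipschitz estimate matches the closed-form spectral maximum", {
  # identity operator: single plane whose spectrum is flat and unit
  ident <- array(0, c(16, 16, 1)); ident[1, 1, 1] <- 1
  expect_equal(lipschitz_estimate(ident, method = "spectral"), 2)
  expect_equal(lipschitz_estimate(ident, n_power_iter = 30,
                                  method = "power"), 2, tolerance = 1e-9)

  I <- sim_intensity(3, n = 64, z = c(-1000, 0, 1000, 2000))
  resp <- fluorescence_response(I, 1.4)
  # independent closed-form oracle: per-frequency sum of plane spectra
  s2 <- Reduce(`+`, lapply(1:4, function(iz)
    Mod(stats::fft(resp[, , iz]))^2))
  L_oracle <- 2 * max(s2)
  expect_equal(lipschitz_estimate(resp, method = "spectral"), L_oracle,
               tolerance = 1e-12)
  L_pow <- lipschitz_estimate(resp, n_power_iter = 200, method = "power")
  expect_lt(abs(L_pow - L_oracle) / L_oracle, 0.01)

  # monotone nondecreasing in the number of planes
  Ls <- vapply(1:4, function(nz)
    lipschitz_estimate(resp[, , 1:nz, drop = FALSE], method = "spectral"),
    numeric(1))
  expect_true(all(diff(Ls) >= 0))
})

test_that("least-squares consistency: lambda = 0 recovers a point source", {
  I <- sim_intensity(9, n = 64, z = 0)
  resp <- fluorescence_response(I, 0, ref_plane = 1)
  ph <- beads(c(64, 64, 1), matrix(c(17, 44, 1), 1))
  img <- scan_image(ph, resp)
  res <- fista(img, resp, fista_params(lambda_reg = 0, n_iter = 300))
  est <- res$estimate$density[, , 1]
  pk <- which(est == max(est), arr.ind = TRUE)
  expect_equal(as.integer(pk[1, ]), c(17, 44))
  # residual of the solved system shrinks far below the data norm
  b0 <- img$values - mean(img$values)
  expect_lt(res$residual_norm / sqrt(sum(b0^2)), 0.05)
})

test_that("the l1 null threshold forces the zero solution", {
  I <- sim_intensity(10, n = 32, z = c(0, 1500))
  resp <- fluorescence_response(I, 0, ref_plane = 1)
  ph <- beads(c(32, 32, 2), matrix(c(10, 20, 1), 1))
  img <- scan_image(ph, resp)
  # raw operator: the literal objective of the model
  lam_raw <- 2 * max(abs(adjoint_At(img$values, resp)))
  res_raw <- fista(img, resp,
                   fista_params(lambda_reg = lam_raw * 1.001, n_iter = 50,
                                demean = FALSE))
  expect_true(all(res_raw$estimate$density == 0))
  # demeaned path: same property against the demeaned operator
  resp_d <- resp
  for (iz in 1:2) resp_d[, , iz] <- resp_d[, , iz] - mean(resp_d[, , iz])
  lam_d <- 2 * max(abs(adjoint_At(img$values - mean(img$values), resp_d)))
  res_d <- fista(img, resp, fista_params(lambda_reg = lam_d * 1.001,
                                         n_iter = 50))
  expect_true(all(res_d$estimate$density == 0))
})

test_that("objective trace is monotone under the restart safeguard", {
  I <- sim_intensity(12, n = 48, z = c(-1500, 0, 1500))
  resp <- fluorescence_response(I, 1.4)
  ph <- random_sparse(c(48, 48, 3), K = 6, seed = 2, min_separation = 8)
  img <- scan_image(ph, resp)
  res <- fista(img, resp, fista_params(lambda_reg = 0.5, n_iter = 150))
  tr <- res$objective_trace
  expect_true(all(is.finite(tr)))
  expect_true(all(diff(tr) <= 1e-9 * pmax(1, abs(tr[-length(tr)]))))
  expect_lte(tr[length(tr)], tr[1])
})

test_that("step-size preconditions are enforced", {
  ident <- array(0, c(8, 8, 1)); ident[1, 1, 1] <- 1
  b <- matrix(1, 8, 8)
  expect_error(fista(b, ident, fista_params(step = 10, n_iter = 5)),
               "1/L")
  # override flag reproduces the fixed-small-step regime
  res <- fista(b, ident, fista_params(step = 1e-7, n_iter = 5,
                                      allow_large_step = TRUE,
                                      demean = FALSE))
  expect_s3_class(res, "fista_result")
})

test_that("K = 10 sources are recovered from a single 2D image", {
  # 64 x 64 x 8 grid, noiseless, lambda small, 500 iterations
  cfg <- optical_config(532, 0.77, 1.515, 150, c(64, 64),
                        seq(-3500, 3500, by = 1000))
  stats_by_seed <- vapply(1:10, function(seed) {
    I <- intensity(propagate(build_pupil(cfg, seed = seed)))
    resp <- fluorescence_response(I, 0)
    ph <- random_sparse(c(64, 64, 8), K = 10, seed = seed + 100,
                        min_separation = 600,
                        voxel_size = c(150, 150, 1000))
    img <- scan_image(ph, resp)
    lam <- lambda_for(img, resp)
    res <- fista(img, resp, fista_params(lambda_reg = lam, n_iter = 500))
    est <- res$estimate$density
    gt <- ph$ground_truth
    top <- arrayInd(order(est, decreasing = TRUE)[1:10], dim(est))
    loc_err <- vapply(1:10, function(i)
      min(sqrt((top[, 1] - gt$y[i])^2 + (top[, 2] - gt$x[i])^2 +
                 (top[, 3] - gt$z[i])^2)), numeric(1))
    amp <- est[cbind(gt$y, gt$x, gt$z)]
    c(max_loc = max(loc_err), max_amp_err = max(abs(amp - 1)))
  }, numeric(2))
  expect_lte(median(stats_by_seed["max_loc", ]), 1)
  expect_lt(median(stats_by_seed["max_amp_err", ]), 0.05)
})

test_that("FISTA suppresses out-of-focus background below Wiener's", {
  ratios <- vapply(1:5, function(seed) {
    I <- sim_intensity(seed, n = 128, z = c(0, 3000))
    resp <- fluorescence_response(I, 0, ref_plane = 1)
    ph <- beads(c(128, 128, 2), matrix(c(64, 64, 1), 1))
    img <- scan_image(ph, resp)
    w <- wiener_stack(img, resp)
    lam <- lambda_for(img, resp)
    f <- fista(img, resp, fista_params(lambda_reg = lam, n_iter = 300))
    e_f <- sum(f$estimate$density[, , 2]^2)
    e_w <- sum(w$density[, , 2]^2)
    # same-support check: the two methods agree on the argmax voxel
    expect_equal(which.max(f$estimate$density), which.max(w$density))
    e_f / e_w
  }, numeric(1))
  expect_lte(median(ratios), 0.10)
})

test_that("recovery success shows the K log(N) compressed-sensing budget", {
  # 32 x 32 x 4 grid: M = 1024 measurements, log(N voxels) = log(4096)
  cfg <- optical_config(532, 0.77, 1.515, 150, c(32, 32),
                        seq(-2250, 2250, by = 1500))
  success <- function(K, seed) {
    I <- intensity(propagate(build_pupil(cfg, seed = seed)))
    resp <- fluorescence_response(I, 0)
    ph <- random_sparse(c(32, 32, 4), K = K, seed = seed + 11,
                        min_separation = 450,
                        voxel_size = c(150, 150, 1500))
    img <- scan_image(ph, resp)
    lam <- lambda_for(img, resp)
    res <- fista(img, resp, fista_params(lambda_reg = lam, n_iter = 300))
    est <- res$estimate$density
    gt <- ph$ground_truth
    top <- arrayInd(order(est, decreasing = TRUE)[seq_len(K)], dim(est))
    all(vapply(seq_len(K), function(i)
      min(sqrt((top[, 1] - gt$y[i])^2 + (top[, 2] - gt$x[i])^2 +
                 (top[, 3] - gt$z[i])^2)) <= 1, logical(1)))
  }
  Ks <- c(5, 15, 40)
  rates <- vapply(Ks, function(K)
    mean(vapply(1:6, function(s) success(K, s), logical(1))), numeric(1))
  # small-K regime is reliably recovered; success cannot improve with K
  expect_gte(rates[1], 0.9)
  expect_true(all(diff(rates) <= 1e-9))
  # fitted budget constant from the largest K still recovered >= 90%
  K_ok <- max(Ks[rates >= 0.9])
  C_fit <- (32 * 32) / (K_ok * log(32 * 32 * 4))
  expect_true(sparsity_budget(K_ok, c(32, 32, 4), M = 32 * 32,
                              constant = C_fit))
  message(sprintf(
    "compressed-sensing budget: success>=90%% up to K=%d, fitted C=%.2f",
    K_ok, C_fit))
})
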