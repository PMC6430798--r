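#' FISTA parameters
#'
#' Settings for the accelerated proximal-gradient solve of
#' `min_x ||A x - b||^2 + lambda ||x||_1`, where `A` maps a voxelized 3D
#' object to its single 2D speckle scan image. The objective carries no
#' 1/2 factor, so the gradient is `2 A^T (A x - b)` and the Lipschitz
#' constant of the smooth part is `L = 2 sigma_max(A)^2`.
#'
#' @param lambda_reg Sparsity weight `lambda >= 0`.
#' @param step Gradient step `t > 0`, or `"auto"` for `1 / L` with `L`
#'   from [lipschitz_estimate()]. A numeric step larger than `1 / L` is
#'   rejected unless `allow_large_step = TRUE` (used to reproduce
#'   fixed-small-step regimes such as `t = 1e-7`).
#' @param n_iter Iteration budget.
#' @param nonnegativity Project onto `x >= 0` inside the proximal map
#'   (off by default; fluorophore density is physically nonnegative but
#'   the plain l1 objective has no such constraint).
#' @param seed Seed for the randomised start of the internal Lipschitz
#'   power iteration only.
#' @param allow_large_step Skip the `step <= 1/L` check.
#' @param demean Solve the exactly equivalent mean-subtracted system
#'   (default). The identity `b - mean(b) = sum_z corr(O_z, F_z - <F_z>)`
#'   removes the DC row of `A`, whose spectral weight `(N <F>)^2` exceeds
#'   every structural frequency by a factor of order the pixel count and
#'   would otherwise shrink the auto step (and hence the convergence rate
#'   of the structure) by that same factor. Set `FALSE` to iterate on the
#'   raw operator.
#' @return An object of class `fista_params`.
#' @export
fista_params <- function(lambda_reg = 0, step = "auto", n_iter = 200,
                         nonnegativity = FALSE, seed = 1,
                         allow_large_step = FALSE, demean = TRUE) {
  stopifnot(lambda_reg >= 0, n_iter >= 1)
  if (is.numeric(step)) stopifnot(step > 0)
  else if (!identical(step, "auto")) stop("`step` must be numeric or \"auto\"")
  structure(list(lambda_reg = lambda_reg, step = step,
                 n_iter = as.integer(n_iter),
                 nonnegativity = isTRUE(nonnegativity),
                 seed = as.integer(seed),
                 allow_large_step = isTRUE(allow_large_step),
                 demean = isTRUE(demean)),
            class = "fista_params")
}

#' Forward projection of a 3D object to its 2D scan image
#'
#' The measurement operator `A` of the compressed-sensing model: identical
#' code path to [scan_image()] (per-plane circular cross-correlation with
#' the response, summed over planes).
#'
#' @param x An [object3d()] or a numeric array `c(ny, nx, nz)`.
#' @param response Response stack `c(ny, nx, nz)`.
#' @return Numeric matrix `b = A x`.
#' @export
forward_A <- function(x, response) {
  dens <- if (inherits(x, "object3d")) x$density else x
  if (is.matrix(dens)) dim(dens) <- c(dim(dens), 1L)
  if (is.matrix(response)) dim(response) <- c(dim(response), 1L)
  if (!all(dim(dens) == dim(response)))
    stop("object and response grids differ", call. = FALSE)
  forward_operator(dens, response_fft(response))
}

#' Adjoint projection of a 2D residual into object space
#'
#' `A^T r`: per-plane circular convolution of the 2D array with each
#' response plane, stacked over z. Satisfies the adjoint identity
#' `<A x, r> = <x, A^T r>` to numerical precision.
#'
#' @param r Numeric matrix (scan-image shaped).
#' @param response Response stack `c(ny, nx, nz)`.
#' @return Numeric array `c(ny, nx, nz)`.
#' @export
adjoint_At <- function(r, response) {
  if (is.matrix(response)) dim(response) <- c(dim(response), 1L)
  if (!all(dim(r) == dim(response)[1:2]))
    stop("residual and response grids differ", call. = FALSE)
  adjoint_operator(r, response_fft(response))
}

#' Soft-thresholding proximal map of the l1 penalty
#'
#' `sign(v) * max(|v| - theta, 0)`; with `nonneg = TRUE` it becomes
#' `max(v - theta, 0)`, the proximal map of l1 plus a nonnegativity
#' constraint.
#'
#' @param v Numeric array.
#' @param theta Threshold >= 0.
#' @param nonneg Apply the nonnegative variant.
#' @return Array of the same shape.
#' @export
soft_threshold <- function(v, theta, nonneg = FALSE) {
  stopifnot(theta >= 0)
  if (nonneg) pmax(v - theta, 0) else sign(v) * pmax(abs(v) - theta, 0)
}

#' Lipschitz constant of the data-fidelity gradient
#'
#' The gradient of `||A x - b||^2` is 2-Lipschitz in the spectral norm of
#' `A`: `L = 2 sigma_max(A)^2`. Because the forward operator is diagonal in
#' the 2D frequency domain, `sigma_max(A)^2 = max_k sum_z |F_hat_z(k)|^2`
#' is available in closed form (`method = "spectral"`, the default);
#' `method = "power"` runs power iteration on `A^T A` from a random start
#' and converges to the same value.
#'
#' @param response Response stack `c(ny, nx, nz)`.
#' @param n_power_iter Power-iteration count (>= 5) for `method = "power"`.
#' @param seed Seed for the random start vector.
#' @param method `"spectral"` (closed form) or `"power"`.
#' @return Estimate of `L`.
#' @export
lipschitz_estimate <- function(response, n_power_iter = 50, seed = 1,
                               method = c("spectral", "power")) {
  method <- match.arg(method)
  if (is.matrix(response)) dim(response) <- c(dim(response), 1L)
  rfft <- response_fft(response)
  if (method == "spectral") {
    s2 <- apply(Mod(rfft)^2, c(1, 2), sum)
    return(2 * max(s2))
  }
  stopifnot(n_power_iter >= 5)
  d <- dim(response)
  x <- withr::with_seed(as.integer(seed),
                        array(stats::rnorm(prod(d)), d))
  x <- x / sqrt(sum(x^2))
  lam <- 0
  for (i in seq_len(n_power_iter)) {
    y <- adjoint_operator(forward_operator(x, rfft), rfft)
    lam <- sum(x * y)                 # Rayleigh quotient for ||x|| = 1
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) return(0)
    x <- y / nrm
  }
  2 * lam
}

#' FISTA solve of the single-image 3D inverse problem
#'
#' Beck-Teboulle fast iterative shrinkage-thresholding for
#' `min_x ||A x - b||^2 + lambda ||x||_1`, recovering a sparse 3D object
#' from its single 2D speckle scan image. Iteration: gradient step
#' `x_tilde = y_k - t * 2 A^T (A y_k - b)`, proximal step
#' `x_{k+1} = soft_threshold(x_tilde, t * lambda)`, momentum
#' `alpha_{k+1} = (1 + sqrt(1 + 4 alpha_k^2)) / 2`,
#' `y_{k+1} = x_{k+1} + ((alpha_k - 1)/alpha_{k+1}) (x_{k+1} - x_k)`,
#' starting from `x_0 = 0`, `alpha_1 = 1`. Plain FISTA is not monotone, so
#' when the objective increases the momentum is restarted and the step
#' retaken from the previous iterate, which guarantees a non-increasing
#' objective trace for `t <= 1/L` without changing the fixed points.
#'
#' @param b A `scan_image` or numeric matrix (the measured image).
#' @param response Response stack `c(ny, nx, nz)` (the 3D speckle PSF).
#' @param params A [fista_params()].
#' @return An object of class `fista_result`: `estimate` ([object3d()]),
#'   `objective_trace`, `residual_norm`, `n_nonzero`, `converged`,
#'   `step_used`, `lipschitz`. Objective and residual refer to the system
#'   actually iterated (the mean-subtracted one when `demean = TRUE`).
#' @export
fista <- function(b, response, params = fista_params()) {
  bm <- if (inherits(b, "scan_image")) b$values else b
  stopifnot(is.matrix(bm), inherits(params, "fista_params"))
  if (is.matrix(response)) dim(response) <- c(dim(response), 1L)
  if (!all(dim(bm) == dim(response)[1:2]))
    stop("image and response grids differ", call. = FALSE)
  if (params$demean) {
    # exact reformulation: per-plane mean subtraction of the response and
    # global mean subtraction of the image remove the dominant DC row
    for (iz in seq_len(dim(response)[3]))
      response[, , iz] <- response[, , iz] - mean(response[, , iz])
    bm <- bm - mean(bm)
  }
  rfft <- response_fft(response)
  d <- dim(response)

  L <- lipschitz_estimate(response, method = "spectral")
  step <- params$step
  if (identical(step, "auto")) {
    if (!(is.finite(L) && L > 0))
      stop("auto step requires a successful Lipschitz estimate", call. = FALSE)
    step <- 1 / L
  } else if (step > 1 / L && !params$allow_large_step) {
    stop(sprintf(
      "step = %g exceeds 1/L = %g; FISTA requires step <= 1/L (set allow_large_step = TRUE to override)",
      step, 1 / L), call. = FALSE)
  }
  lam <- params$lambda_reg
  nn <- params$nonnegativity

  objective <- function(x) {
    r <- forward_operator(x, rfft) - bm
    sum(r^2) + lam * sum(abs(x))
  }
  prox_step <- function(y) {
    g <- 2 * adjoint_operator(forward_operator(y, rfft) - bm, rfft)
    soft_threshold(y - step * g, step * lam, nonneg = nn)
  }

  x_prev <- array(0, d)
  y <- x_prev
  alpha <- 1
  obj_prev <- objective(x_prev)
  trace <- numeric(params$n_iter + 1)
  trace[1] <- obj_prev
  for (k in seq_len(params$n_iter)) {
    x_new <- prox_step(y)
    obj_new <- objective(x_new)
    if (obj_new > obj_prev) {
      # monotone safeguard: drop momentum, plain ISTA step from x_prev
      alpha <- 1
      x_new <- prox_step(x_prev)
      obj_new <- objective(x_new)
      if (obj_new > obj_prev + 1e-9 * max(1, abs(obj_prev))) {
        # a monotone step must succeed when step <= 1/L
        x_new <- x_prev
        obj_new <- obj_prev
      }
    }
    if (!is.finite(obj_new))
      stop("FISTA diverged (non-finite objective); step-size precondition step <= 1/L violated?",
           call. = FALSE)
    alpha_new <- (1 + sqrt(1 + 4 * alpha^2)) / 2
    y <- x_new + ((alpha - 1) / alpha_new) * (x_new - x_prev)
    x_prev <- x_new
    alpha <- alpha_new
    trace[k + 1] <- obj_new
    obj_prev <- obj_new
  }
  res <- forward_operator(x_prev, rfft) - bm
  n_tr <- length(trace)
  converged <- n_tr >= 2 &&
    abs(trace[n_tr] - trace[n_tr - 1]) <= 1e-8 * max(1, abs(trace[n_tr]))
  structure(
    list(estimate = object3d(x_prev, validate = FALSE),
         objective_trace = trace,
         residual_norm = sqrt(sum(res^2)),
         n_nonzero = sum(x_prev != 0),
         converged = converged,
         step_used = step, lipschitz = L,
         params = params),
    class = "fista_result")
}

#' @export
print.fista_result <- function(x, ...) {
  n <- length(x$objective_trace)
  cat(sprintf(
    "<fista_result> %d iter, objective %.6g -> %.6g, ||r|| = %.4g, %d nonzero\n",
    n - 1, x$objective_trace[1], x$objective_trace[n], x$residual_norm,
    x$n_nonzero))
  invisible(x)
}

#' Grid search for the sparsity weight against a known ground truth
#'
#' Test-time helper: runs FISTA over a grid of `lambda` values and returns
#' the one minimising the root-mean-squared error against a known phantom.
#' Intended for simulation studies only; user-facing reconstruction never
#' has access to the truth.
#'
#' @param b A `scan_image` or matrix.
#' @param response Response stack.
#' @param truth An [object3d()] ground-truth phantom.
#' @param lambdas Candidate `lambda` values.
#' @param ... Further arguments to [fista_params()].
#' @return List with `lambda`, `rmse`, and the winning `fista_result`.
#' @export
select_lambda_rmse <- function(b, response, truth, lambdas, ...) {
  stopifnot(inherits(truth, "object3d"), length(lambdas) >= 1)
  best <- NULL
  for (l in lambdas) {
    res <- fista(b, response, fista_params(lambda_reg = l, ...))
    rmse <- sqrt(mean((res$estimate$density - truth$density)^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(lambda = l, rmse = rmse, result = res)
  }
  best
}
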