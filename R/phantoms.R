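#' Voxelized 3D object
#'
#' Container for a nonnegative fluorophore density on a `c(ny, nx, nz)`
#' voxel grid, together with the exact ground truth used by recovery tests.
#' Voxels may be anisotropic: `voxel_size = c(dy, dx, dz)` in nm, matching
#' the typical situation of 50-100 nm transverse pixels and ~1 um plane
#' spacing.
#'
#' @param density Nonnegative numeric array `c(ny, nx, nz)`.
#' @param voxel_size Numeric `c(dy, dx, dz)` in nm.
#' @param ground_truth Optional data frame with columns `y`, `x`, `z`
#'   (voxel coordinates, 1-based, possibly fractional), `diameter` (nm) and
#'   `amplitude`.
#' @param validate Check nonnegativity (internal estimates skip this).
#' @return An object of class `object3d`.
#' @export
object3d <- function(density, voxel_size = c(1, 1, 1), ground_truth = NULL,
                     validate = TRUE) {
  if (length(dim(density)) == 2) dim(density) <- c(dim(density), 1L)
  stopifnot(length(dim(density)) == 3, length(voxel_size) == 3)
  if (validate && any(density < 0))
    stop("object density must be nonnegative", call. = FALSE)
  if (!is.null(ground_truth)) {
    stopifnot(all(c("y", "x", "z") %in% names(ground_truth)))
    d <- dim(density)
    ok <- ground_truth$y >= 1 & ground_truth$y <= d[1] &
      ground_truth$x >= 1 & ground_truth$x <= d[2] &
      ground_truth$z >= 1 & ground_truth$z <= d[3]
    if (!all(ok)) stop("ground-truth positions outside the grid", call. = FALSE)
  }
  structure(list(density = density, voxel_size = as.numeric(voxel_size),
                 ground_truth = ground_truth),
            class = "object3d")
}

#' @export
print.object3d <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("<object3d> %d x %d x %d voxels (%g x %g x %g nm), %d nonzero\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], sum(x$density != 0)))
  invisible(x)
}

# Deterministic lattice of sample points filling a sphere of given
# diameter; used for partial-volume rasterisation.
sphere_points <- function(diameter, step) {
  r <- diameter / 2
  g <- seq(-r, r, by = step)
  pts <- as.matrix(expand.grid(dy = g, dx = g, dz = g))
  pts[rowSums(pts^2) <= r^2 + 1e-12, , drop = FALSE]
}

#' Spherical bead phantom
#'
#' Rasterizes fluorescent beads as filled density spheres with
#' partial-volume (edge antialiasing) weighting: each bead's integrated
#' density equals its amplitude regardless of sub-voxel position, so
#' recovery tests are amplitude-homogeneous. `diameter = 0` gives an ideal
#' point source occupying a single voxel.
#'
#' @param shape Integer `c(ny, nx, nz)` grid shape.
#' @param positions Numeric matrix with one row per bead and columns
#'   `(y, x, z)` in voxel coordinates (1-based, fractional allowed).
#' @param diameter Bead diameter in nm (one value for all beads).
#' @param amplitudes Per-bead total integrated density; recycled.
#' @param voxel_size `c(dy, dx, dz)` in nm.
#' @return An [object3d()] carrying the exact bead list as ground truth.
#' @export
beads <- function(shape, positions, diameter = 0, amplitudes = 1,
                  voxel_size = c(1, 1, 1)) {
  shape <- as.integer(shape)
  positions <- matrix(as.numeric(positions), ncol = 3)
  amplitudes <- rep_len(amplitudes, nrow(positions))
  stopifnot(diameter >= 0)
  dens <- array(0, shape)
  vs <- as.numeric(voxel_size)
  for (b in seq_len(nrow(positions))) {
    p <- positions[b, ]
    if (any(p < 0.5) || any(p > shape + 0.5))
      stop("bead position outside the grid", call. = FALSE)
    if (diameter == 0) {
      v <- pmin(pmax(round(p), 1), shape)
      dens[v[1], v[2], v[3]] <- dens[v[1], v[2], v[3]] + amplitudes[b]
    } else {
      pts <- sphere_points(diameter, step = min(vs) / 6)
      # physical offsets -> voxel indices of each sample point
      iy <- pmin(pmax(round(p[1] + pts[, 1] / vs[1]), 1), shape[1])
      ix <- pmin(pmax(round(p[2] + pts[, 2] / vs[2]), 1), shape[2])
      iz <- pmin(pmax(round(p[3] + pts[, 3] / vs[3]), 1), shape[3])
      w <- amplitudes[b] / nrow(pts)
      idx <- cbind(iy, ix, iz)
      for (r in seq_len(nrow(idx)))
        dens[idx[r, 1], idx[r, 2], idx[r, 3]] <-
          dens[idx[r, 1], idx[r, 2], idx[r, 3]] + w
    }
  }
  gt <- data.frame(y = positions[, 1], x = positions[, 2], z = positions[, 3],
                   diameter = diameter, amplitude = amplitudes)
  object3d(dens, voxel_size, gt)
}

#' Random K-sparse point-source phantom
#'
#' K unit-amplitude point sources at uniformly random voxel positions,
#' subject to a minimum pairwise (physical) separation enforced by
#' rejection sampling. This is the canonical object for compressed-sensing
#' recovery experiments.
#'
#' @param shape Integer `c(ny, nx, nz)`.
#' @param K Number of sources (0 gives an empty object).
#' @param seed Integer seed (fixed seed gives an identical object).
#' @param min_separation Minimum pairwise distance in nm.
#' @param voxel_size `c(dy, dx, dz)` in nm.
#' @param amplitudes Source amplitudes, recycled to length K.
#' @param max_tries Rejection-sampling retry cap per source.
#' @return An [object3d()] with the source list as ground truth.
#' @export
random_sparse <- function(shape, K, seed, min_separation = 0,
                          voxel_size = c(1, 1, 1), amplitudes = 1,
                          max_tries = 2000) {
  shape <- as.integer(shape)
  K <- as.integer(K)
  vs <- as.numeric(voxel_size)
  pos <- withr::with_seed(as.integer(seed), {
    acc <- matrix(numeric(0), ncol = 3)
    for (k in seq_len(K)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- c(sample.int(shape[1], 1), sample.int(shape[2], 1),
                  sample.int(shape[3], 1))
        if (nrow(acc) == 0) { ok <- TRUE } else {
          d2 <- ((acc[, 1] - cand[1]) * vs[1])^2 +
            ((acc[, 2] - cand[2]) * vs[2])^2 +
            ((acc[, 3] - cand[3]) * vs[3])^2
          ok <- all(d2 >= min_separation^2)
        }
        if (ok) { acc <- rbind(acc, cand); placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place ", K, " sources at this separation; ",
             "reduce K or min_separation", call. = FALSE)
    }
    acc
  })
  if (K == 0)
    return(object3d(array(0, shape), voxel_size,
                    data.frame(y = numeric(0), x = numeric(0),
                               z = numeric(0), diameter = numeric(0),
                               amplitude = numeric(0))))
  beads(shape, pos, diameter = 0, amplitudes = amplitudes,
        voxel_size = voxel_size)
}

#' Dense random single-plane layer
#'
#' A thin uniform layer of fluorophores confined to one z-plane: the object
#' used for saturation-curve experiments, where the measured signal is the
#' speckle-averaged fluorescence.
#'
#' @param shape Integer `c(ny, nx, nz)`.
#' @param z_index Plane carrying the layer.
#' @param fill_fraction Fraction of occupied pixels in (0, 1].
#' @param seed Integer seed.
#' @param voxel_size `c(dy, dx, dz)` in nm.
#' @return An [object3d()] (no bead-style ground truth).
#' @export
dense_layer <- function(shape, z_index, fill_fraction, seed,
                        voxel_size = c(1, 1, 1)) {
  shape <- as.integer(shape)
  stopifnot(fill_fraction > 0, fill_fraction <= 1,
            z_index >= 1, z_index <= shape[3])
  dens <- array(0, shape)
  plane <- withr::with_seed(as.integer(seed), {
    matrix(as.numeric(stats::runif(shape[1] * shape[2]) < fill_fraction),
           shape[1], shape[2])
  })
  if (fill_fraction == 1) plane[] <- 1
  dens[, , z_index] <- plane
  object3d(dens, voxel_size)
}

#' Random filament phantom
#'
#' Smooth random 3D curves rasterized with a one-voxel cross-section,
#' emulating cytoskeletal filaments; intended for qualitative and
#' dense-object stress tests only. Each filament is a direction random walk
#' with small angular steps, reflected at the grid boundary, walked at
#' half-voxel arc-length steps and rasterized at unit arc spacing (so the
#' voxel count tracks the Euclidean arc length while consecutive marks
#' stay 26-connected).
#'
#' @param shape Integer `c(ny, nx, nz)`.
#' @param n_filaments Number of curves.
#' @param seed Integer seed.
#' @param length_voxels Arc length of each curve, in transverse-voxel
#'   units.
#' @param voxel_size `c(dy, dx, dz)` in nm.
#' @param wobble Std-dev (radians) of the per-step direction perturbation.
#' @return An [object3d()]; attribute `arc_length_voxels` records the total
#'   generated arc length.
#' @export
filaments <- function(shape, n_filaments, seed, length_voxels = 40,
                      voxel_size = c(1, 1, 1), wobble = 0.08) {
  shape <- as.integer(shape)
  dens <- array(0, shape)
  total_len <- 0
  dens <- withr::with_seed(as.integer(seed), {
    for (f in seq_len(n_filaments)) {
      p <- stats::runif(3, min = 1, max = shape)
      dir <- stats::rnorm(3); dir[3] <- dir[3] * 0.3  # mostly transverse
      dir <- dir / sqrt(sum(dir^2))
      step <- 0.5
      n_steps <- round(length_voxels / step)
      for (i in seq_len(n_steps)) {
        dir <- dir + stats::rnorm(3, sd = wobble)
        dir <- dir / sqrt(sum(dir^2))
        p_new <- p + dir * step
        # reflect at boundaries
        for (a in 1:3) {
          if (p_new[a] < 1) { p_new[a] <- 2 - p_new[a]; dir[a] <- -dir[a] }
          if (p_new[a] > shape[a]) {
            p_new[a] <- 2 * shape[a] - p_new[a]; dir[a] <- -dir[a]
          }
        }
        p <- p_new
        total_len <- total_len + step
        if (i %% 2 == 0) {  # mark at unit arc spacing
          v <- pmin(pmax(round(p), 1), shape)
          dens[v[1], v[2], v[3]] <- 1
        }
      }
    }
    dens
  })
  out <- object3d(dens, voxel_size)
  attr(out, "arc_length_voxels") <- n_filaments * length_voxels
  out
}
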