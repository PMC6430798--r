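#' Validate a run configuration
#'
#' A run configuration is a nested list (typically parsed from JSON)
#' describing an end-to-end experiment: optical block, saturation levels,
#' phantom, optional noise, and reconstruction method. Every random
#' operation consumes an explicit seed recorded in the outputs.
#'
#' Blocks and keys:
#' \itemize{
#'   \item `optical`: `wavelength`, `na`, `medium_index`, `pixel_size_xy`,
#'     `grid_shape` (ny, nx), `z_planes`.
#'   \item `saturation`: `s_mean` (vector; 0 = linear).
#'   \item `phantom`: `type` in `beads | random_sparse | dense_layer |
#'     filaments` plus that generator's parameters and `seed`.
#'   \item `noise` (optional): `photons_at_mean`, `background`, `seed`.
#'   \item `reconstruction`: `method` in `wiener | fista | crosscorr`,
#'     plus `noise_psd` (wiener) or `lambda_reg` / `n_iter` (fista).
#'   \item `seed`: pupil seed.
#' }
#'
#' @param config Nested list.
#' @return The validated config, invisibly; errors list every offending
#'   key.
#' @export
validate_run_config <- function(config) {
  problems <- character(0)
  need <- function(block, keys) {
    if (is.null(config[[block]])) {
      problems <<- c(problems, sprintf("missing block '%s'", block))
      return(invisible(NULL))
    }
    miss <- setdiff(keys, names(config[[block]]))
    if (length(miss))
      problems <<- c(problems, sprintf("block '%s': missing key(s) %s",
                                       block, paste(miss, collapse = ", ")))
  }
  need("optical", c("wavelength", "na", "pixel_size_xy", "grid_shape",
                    "z_planes"))
  need("saturation", "s_mean")
  need("phantom", c("type", "seed"))
  need("reconstruction", "method")
  if (is.null(config$seed)) problems <- c(problems, "missing key 'seed'")
  if (!is.null(config$reconstruction$method) &&
      !config$reconstruction$method %in% c("wiener", "fista", "crosscorr"))
    problems <- c(problems,
                  "reconstruction$method must be wiener, fista or crosscorr")
  if (!is.null(config$phantom$type) &&
      !config$phantom$type %in% c("beads", "random_sparse", "dense_layer",
                                  "filaments"))
    problems <- c(problems, "unknown phantom$type")
  if (length(problems))
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  invisible(config)
}

build_phantom <- function(ph, cfg) {
  shape <- c(cfg$grid_shape, length(cfg$z_planes))
  dz <- if (length(cfg$z_planes) > 1) mean(diff(cfg$z_planes)) else
    cfg$pixel_size_xy
  vs <- c(cfg$pixel_size_xy, cfg$pixel_size_xy, dz)
  switch(ph$type,
    beads = beads(shape, matrix(unlist(ph$positions), ncol = 3,
                                byrow = TRUE),
                  diameter = ph$diameter %||% 0,
                  amplitudes = ph$amplitudes %||% 1, voxel_size = vs),
    random_sparse = random_sparse(shape, K = ph$K, seed = ph$seed,
                                  min_separation = ph$min_separation %||% 0,
                                  voxel_size = vs),
    dense_layer = dense_layer(shape, z_index = ph$z_index,
                              fill_fraction = ph$fill_fraction,
                              seed = ph$seed, voxel_size = vs),
    filaments = filaments(shape, n_filaments = ph$n_filaments,
                          seed = ph$seed, voxel_size = vs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a simulate/scan/reconstruct/measure experiment
#'
#' End-to-end orchestration: simulates the speckle response stack (linear
#' plus each requested saturation level), renders the phantom, forms the
#' single 2D scan image per response, optionally adds Poisson noise,
#' reconstructs with the requested method, and writes every artifact
#' (TIFF stacks, scan images, reconstructions) together with a JSON
#' metrics report to the output directory.
#'
#' @param config Run configuration (see [validate_run_config()]).
#' @param out_dir Output directory, created if needed.
#' @return The metrics report list, invisibly; all artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  oc <- config$optical
  cfg <- optical_config(oc$wavelength, oc$na, oc$medium_index %||% 1.0,
                        oc$pixel_size_xy, unlist(oc$grid_shape),
                        unlist(oc$z_planes))
  t0 <- Sys.time()
  log_lines <- c(sprintf("specklescope %s | R %s",
                         as.character(utils::packageVersion("specklescope")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("pupil seed %d", as.integer(config$seed)))
  pupil <- build_pupil(cfg, seed = config$seed)
  vol <- propagate(pupil)
  I <- intensity(vol)
  phantom <- build_phantom(config$phantom, cfg)
  write_stack(phantom$density, file.path(out_dir, "phantom.tif"),
              metadata = list(ground_truth = phantom$ground_truth,
                              seed = config$phantom$seed))

  s_levels <- unique(c(0, unlist(config$saturation$s_mean)))
  report <- list(seed = config$seed, s_levels = s_levels,
                 grain_sizes = grain_sizes(cfg), metrics = list())
  for (s in s_levels) {
    tag <- if (s == 0) "linear" else sprintf("s%g", s)
    resp <- fluorescence_response(I, s_mean = s)
    write_stack(resp, file.path(out_dir, sprintf("response_%s.tif", tag)),
                metadata = list(config = unclass(cfg), seed = config$seed,
                                s_mean = s))
    img <- scan_image(phantom, resp)
    if (!is.null(config$noise))
      img <- apply_noise(img, config$noise$photons_at_mean,
                         config$noise$background %||% 0,
                         config$noise$seed %||% 1)
    write_stack(img$values, file.path(out_dir, sprintf("scan_%s.tif", tag)))
    rec <- switch(config$reconstruction$method,
      wiener = wiener_stack(img, resp,
        wiener_params(config$reconstruction$noise_psd %||% NULL)),
      crosscorr = crosscorr_project(img, resp),
      fista = fista(img, resp,
        fista_params(lambda_reg = config$reconstruction$lambda_reg %||% 0,
                     n_iter = config$reconstruction$n_iter %||% 200))$estimate)
    write_stack(rec$density, file.path(out_dir, sprintf("recon_%s.tif", tag)))

    m <- list(s_mean = s, scan_mean = mean(img$values))
    curve <- tryCatch(axial_correlation_curve(resp),
                      error = function(e) NULL)
    if (!is.null(curve)) m$axial_corr_fwhm_nm <- curve$fwhm
    if (!is.null(phantom$ground_truth) && nrow(phantom$ground_truth) > 0)
      m$snr <- reconstruction_snr(rec, phantom)
    report$metrics[[tag]] <- m
    log_lines <- c(log_lines, sprintf("level %s done", tag))
  }
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(report)
}
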