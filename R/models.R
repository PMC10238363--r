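#' Analytic attenuated forward projection
#'
#' Rotation-based parallel-beam projector: for each angle the volume is
#' resampled (bilinear) onto a frame aligned with the rays, and each
#' detector bin accumulates `activity * voxel_size * exp(-optical path to
#' the detector) * sensitivity * time`. With `cdr = "on"` each constant-depth
#' slab is additionally blurred with a Gaussian of the distance-dependent
#' collimator FWHM before summation. The output is linear in `activity`.
#'
#' Detector bins are tied to the grid: `det_bins` must equal `(nx, nz)` and
#' the bin size must equal the voxel size.
#'
#' @param activity 3-D array of activity concentration (Bq/ml).
#' @param mu 3-D array of linear attenuation coefficients (1/mm) at the
#'   energy being modelled.
#' @param geom a [system_geometry()].
#' @param grid the [voxel_grid()] shared by `activity` and `mu`.
#' @param cdr `"off"` (attenuation only) or `"on"` (adds the
#'   distance-dependent Gaussian collimator response).
#' @param angles_idx optional integer vector of angle indices (1-based) to
#'   project; default all.
#' @return a [sinogram()] of kind `"expectation"` (or a plain array when
#'   `angles_idx` is a subset, for use inside reconstruction loops).
#' @export
analytic_forward <- function(activity, mu, geom, grid, cdr = c("off", "on"),
                             angles_idx = NULL) {
  cdr <- match.arg(cdr)
  check_projector_inputs(activity, mu, geom, grid)
  subset <- !is.null(angles_idx)
  if (!subset) angles_idx <- seq_len(geom$n_proj)
  sino <- cpp_forward_project(
    as.numeric(activity), as.numeric(mu), grid$dims, grid$voxel_size,
    geom$angles_deg[angles_idx] * pi / 180, geom$orbit_radius_mm[angles_idx],
    geom$sensitivity * geom$time_per_proj_s,
    cdr == "on", geom$collimator$fwhm_intrinsic, geom$collimator$fwhm_slope)
  if (subset) return(sino)
  sinogram(sino, geom, kind = "expectation")
}

#' Analytic attenuated back projection (adjoint)
#'
#' Exact matrix transpose of [analytic_forward()] with the same options, as
#' required by the multiplicative OSEM update.
#'
#' @param sino a [sinogram()] or plain `(nu, nv, n_angles)` array.
#' @inheritParams analytic_forward
#' @return 3-D volume array.
#' @export
analytic_adjoint <- function(sino, mu, geom, grid, cdr = c("off", "on"),
                             angles_idx = NULL) {
  cdr <- match.arg(cdr)
  v <- if (inherits(sino, "sinogram")) sino$values else sino
  if (is.null(angles_idx)) angles_idx <- seq_len(geom$n_proj)
  cpp_back_project(
    as.numeric(v), as.numeric(mu), grid$dims, grid$voxel_size,
    geom$angles_deg[angles_idx] * pi / 180, geom$orbit_radius_mm[angles_idx],
    geom$sensitivity * geom$time_per_proj_s,
    cdr == "on", geom$collimator$fwhm_intrinsic, geom$collimator$fwhm_slope)
}

check_projector_inputs <- function(activity, mu, geom, grid) {
  if (!identical(dim(activity), as.integer(grid$dims)))
    stop("activity dims do not match grid")
  if (!identical(dim(mu), as.integer(grid$dims)))
    stop("mu dims do not match grid; activity and mu must share a grid")
  if (!identical(geom$det_bins, as.integer(grid$dims[c(1, 3)])))
    stop("det_bins must equal grid dims (nx, nz) for the projector")
  if (abs(geom$bin_size - grid$voxel_size) > 1e-9)
    stop("detector bin size must equal the voxel size")
  body_extent <- max(grid$dims[1:2]) * grid$voxel_size / 2
  if (any(geom$orbit_radius_mm < body_extent))
    stop("geometry error: orbit radius ", min(geom$orbit_radius_mm),
         " mm is smaller than the body extent ", round(body_extent, 1), " mm")
  invisible(TRUE)
}

#' Monte Carlo photon-transport forward projection
#'
#' Samples emission points proportional to activity, assigns each photon a
#' photopeak (171 or 245 keV) by abundance, and transports it through the
#' attenuation maps with Woodcock free-path sampling, photoelectric
#' absorption and Klein-Nishina Compton scattering. Two scoring modes:
#'
#' * `mode = "forced"` (default): forced detection — every emission and
#'   every Compton vertex deposits its expected contribution at every
#'   projection angle, attenuated along the ray to the detector and weighted
#'   by the energy-window acceptance; the collimator response is applied as
#'   a sampled Gaussian offset in the detector plane. Efficient and
#'   unbiased; the estimator used inside reconstruction.
#' * `mode = "analog"`: naive analog tracking with a binary acceptance cone
#'   per detector angle; the reference estimator for unbiasedness checks
#'   against the analytic projector in the scatter-free configuration.
#'
#' Transported photons use attenuation interpolated log-linearly in energy
#' between the 171 and 245 keV maps (clamped below 100 keV). The returned
#' sinogram is an unbiased estimate of the count expectation: in the
#' scatter-free configuration its mean over seeds equals the
#' [analytic_forward()] result.
#'
#' @param activity 3-D activity array (Bq/ml); all zero gives an all-zero
#'   sinogram.
#' @param mu_171,mu_245 attenuation maps (1/mm) at the photopeaks.
#' @param geom a [system_geometry()].
#' @param grid the shared [voxel_grid()].
#' @param n_photons photon budget (>= 1).
#' @param seed integer seed.
#' @param scatter logical; include Compton scatter (default TRUE).
#' @param mode `"forced"` or `"analog"`.
#' @param cdr logical; apply the distance-dependent Gaussian collimator
#'   response (forced mode), default TRUE.
#' @param compton_fraction probability that an interaction is Compton
#'   scatter rather than photoelectric absorption, default 0.99
#'   (soft tissue at 171-245 keV).
#' @param energy_res_fwhm fractional FWHM of the Gaussian detector energy
#'   resolution (default 0.10 as at 171 keV; 0 disables smearing).
#' @param accept_half_angle_deg binary acceptance half-angle for analog
#'   mode, default 3 degrees.
#' @param max_orders maximum Compton scatter orders tracked, default 3.
#' @param angles_idx optional angle subset (1-based); when given, a plain
#'   array is returned for use inside reconstruction loops.
#' @return a [sinogram()] of kind `"expectation"` (MC estimate).
#' @export
mc_forward <- function(activity, mu_171, mu_245, geom, grid, n_photons, seed,
                       scatter = TRUE, mode = c("forced", "analog"),
                       cdr = TRUE, compton_fraction = 0.99,
                       energy_res_fwhm = 0.10, accept_half_angle_deg = 3,
                       max_orders = 3L, angles_idx = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n_photons) || n_photons < 1)
    stop("n_photons must be >= 1")
  check_projector_inputs(activity, mu_171, geom, grid)
  subset <- !is.null(angles_idx)
  if (!subset) angles_idx <- seq_len(geom$n_proj)
  wins <- do.call(rbind, lapply(geom$energy_windows, function(w) w[c("lo", "hi")]))
  sino <- with_seed(seed, cpp_mc_forward(
    as.numeric(activity), as.numeric(mu_171), as.numeric(mu_245),
    grid$dims, grid$voxel_size,
    geom$angles_deg[angles_idx] * pi / 180, geom$orbit_radius_mm[angles_idx],
    geom$sensitivity * geom$time_per_proj_s, as.numeric(n_photons),
    wins, geom$photopeak_abundances[["171"]], geom$photopeak_abundances[["245"]],
    scatter, compton_fraction, if (mode == "forced") 0L else 1L,
    accept_half_angle_deg * pi / 180,
    cdr, geom$collimator$fwhm_intrinsic, geom$collimator$fwhm_slope,
    energy_res_fwhm, as.integer(max_orders)))
  if (subset) return(sino)
  sinogram(sino, geom, kind = "expectation", seed = as.integer(seed),
           photon_budget = n_photons)
}

#' Forward/adjoint model pairs for reconstruction
#'
#' `analytic_model()` builds the attenuation-only (optionally CDR-blurred)
#' matched projector pair used by the conventional attenuation-corrected
#' arm. `mc_model()` builds the Monte Carlo-in-the-loop pair: Monte Carlo
#' forward projection with scatter and collimator response, paired with the
#' CDR-corrected analytic attenuated back projection (an unmatched pair, by
#' design). Fresh Monte Carlo seeds are drawn per forward call from a
#' deterministic stream, so updates are unbiased but noisy.
#'
#' @param case a `phantom_case` (supplies attenuation maps and grid).
#' @param geom a [system_geometry()].
#' @param cdr logical; include the collimator response in the analytic pair.
#' @param photons_per_forward Monte Carlo photon budget per forward call.
#' @param seed seed for the Monte Carlo seed stream.
#' @param scatter include Compton scatter in the MC forward.
#' @return a list with elements `forward(x, angles_idx)` and
#'   `adjoint(y, angles_idx)`.
#' @export
analytic_model <- function(case, geom, cdr = FALSE) {
  mu <- case$mu_171
  grid <- case$grid
  cdr_s <- if (cdr) "on" else "off"
  list(
    forward = function(x, angles_idx = NULL)
      analytic_forward(x, mu, geom, grid, cdr = cdr_s, angles_idx = angles_idx),
    adjoint = function(y, angles_idx = NULL)
      analytic_adjoint(y, mu, geom, grid, cdr = cdr_s, angles_idx = angles_idx)
  )
}

#' @rdname analytic_model
#' @export
mc_model <- function(case, geom, photons_per_forward = 2e5, seed = 1,
                     scatter = TRUE) {
  grid <- case$grid
  env <- new.env()
  env$k <- 0L
  list(
    forward = function(x, angles_idx = NULL) {
      env$k <- env$k + 1L
      s <- derive_seeds(seed, env$k)[env$k]
      mc_forward(x, case$mu_171, case$mu_245, geom, grid,
                 n_photons = photons_per_forward, seed = s,
                 scatter = scatter, mode = "forced", cdr = TRUE,
                 angles_idx = angles_idx)
    },
    adjoint = function(y, angles_idx = NULL)
      analytic_adjoint(y, case$mu_171, geom, grid, cdr = "on",
                       angles_idx = angles_idx)
  )
}
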