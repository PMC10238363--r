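#' Collimator-detector response model
#'
#' Distance-dependent Gaussian blur of a parallel-hole collimator plus
#' intrinsic detector resolution: `FWHM(d) = fwhm_intrinsic + fwhm_slope * d`
#' with `d` the source-to-detector-face distance in mm. Defaults are typical
#' of a medium-energy parallel-hole collimator.
#'
#' @param fwhm_intrinsic FWHM in mm at distance 0.
#' @param fwhm_slope FWHM growth in mm per mm distance.
#' @param septal_penetration_fraction fraction of events bypassing the
#'   geometric response (default 0; reserved, not modelled).
#' @return object of class `collimator_model`.
#' @export
collimator_model <- function(fwhm_intrinsic = 4.5, fwhm_slope = 0.045,
                             septal_penetration_fraction = 0) {
  if (fwhm_intrinsic < 0 || fwhm_slope < 0)
    stop("collimator FWHM parameters must be nonnegative")
  structure(list(fwhm_intrinsic = fwhm_intrinsic, fwhm_slope = fwhm_slope,
                 septal_penetration_fraction = septal_penetration_fraction),
            class = "collimator_model")
}

#' Collimator FWHM at a distance
#'
#' @param distance source-to-detector distance in mm (nonnegative).
#' @param collimator a [collimator_model()].
#' @return FWHM in mm.
#' @export
cdr_fwhm <- function(distance, collimator = collimator_model()) {
  if (any(distance < 0)) stop("distance must be >= 0")
  collimator$fwhm_intrinsic + collimator$fwhm_slope * distance
}

#' SPECT acquisition geometry
#'
#' Circular-orbit parallel-beam geometry: `n_proj` projection angles over
#' 360 degrees, a square detector of `det_bins` bins of `bin_size` mm, a
#' per-projection acquisition time, two photopeak energy windows, and a
#' scalar system sensitivity that absorbs geometric efficiency and crystal
#' response. The default emulates a 120 x 30 s In-111 octreotide
#' acquisition on a 128 x 128 matrix at 4.42 mm with two 20% windows at 171
#' and 245 keV.
#'
#' @param n_proj number of projections (>= 4), default 120.
#' @param det_bins detector bins (u, v); default `c(128, 128)`.
#' @param bin_size detector bin size in mm, default 4.42.
#' @param orbit_radius_mm detector-face to rotation-axis distance per angle
#'   (scalar for a circular orbit), default 250.
#' @param time_per_proj_s seconds per projection, default 30.
#' @param energy_windows list of `c(center_keV, fractional_width)` pairs.
#' @param photopeak_abundances photons per decay of the two In-111 gammas
#'   (171, 245 keV).
#' @param collimator a [collimator_model()].
#' @param sensitivity scalar counts per (Bq/ml * mm * s) ray-sum unit; the
#'   default is calibrated so a default phantom acquisition collects a few
#'   million counts, the clinical count level.
#' @param angles_deg optional explicit angles (degrees, strictly
#'   increasing, spanning less than 360 + spacing).
#' @return object of class `system_geometry`.
#' @export
system_geometry <- function(n_proj = 120L,
                            det_bins = c(128L, 128L),
                            bin_size = 4.42,
                            orbit_radius_mm = 250,
                            time_per_proj_s = 30,
                            energy_windows = list(c(171, 0.20), c(245, 0.20)),
                            photopeak_abundances = c("171" = 0.907, "245" = 0.941),
                            collimator = collimator_model(),
                            sensitivity = 2.0e-7,
                            angles_deg = NULL) {
  n_proj <- as.integer(n_proj)
  if (n_proj < 4L) stop("n_proj must be >= 4")
  if (is.null(angles_deg)) angles_deg <- seq(0, 360, length.out = n_proj + 1L)[seq_len(n_proj)]
  if (length(angles_deg) != n_proj) stop("angles_deg length must equal n_proj")
  if (any(diff(angles_deg) <= 0)) stop("angles must be strictly increasing")
  spacing <- if (n_proj > 1) stats::median(diff(angles_deg)) else 360
  if (diff(range(angles_deg)) >= 360 + spacing) stop("angles span too wide")
  orbit <- rep_len(orbit_radius_mm, n_proj)
  wins <- lapply(energy_windows, function(w) {
    c(lo = w[1] * (1 - w[2] / 2), hi = w[1] * (1 + w[2] / 2), center = w[1])
  })
  structure(list(
    n_proj = n_proj, angles_deg = as.numeric(angles_deg),
    det_bins = as.integer(det_bins), bin_size = bin_size,
    orbit_radius_mm = orbit, time_per_proj_s = time_per_proj_s,
    energy_windows = wins, photopeak_abundances = photopeak_abundances,
    collimator = collimator, sensitivity = sensitivity
  ), class = "system_geometry")
}

#' @export
print.system_geometry <- function(x, ...) {
  cat("system_geometry: ", x$n_proj, " projections x ",
      paste(x$det_bins, collapse = "x"), " bins @ ", x$bin_size, " mm, ",
      x$time_per_proj_s, " s/projection, orbit ",
      x$orbit_radius_mm[1], " mm\n", sep = "")
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(a$n_proj, b$n_proj) &&
    isTRUE(all.equal(a$angles_deg, b$angles_deg)) &&
    identical(a$det_bins, b$det_bins) &&
    isTRUE(all.equal(a$bin_size, b$bin_size))
}

#' Sinogram container
#'
#' Projection-space data: a 3-D array indexed (u, v, angle) holding either
#' Poisson count expectations or sampled integer counts.
#'
#' @param values numeric array `det_bins[1] x det_bins[2] x n_proj`,
#'   nonnegative.
#' @param geometry a [system_geometry()].
#' @param kind `"expectation"` or `"counts"`.
#' @param seed seed used to produce the values (or `NA`).
#' @param photon_budget Monte Carlo photon budget (or `NA`).
#' @return object of class `sinogram`.
#' @export
sinogram <- function(values, geometry, kind = c("expectation", "counts"),
                     seed = NA_integer_, photon_budget = NA_real_) {
  kind <- match.arg(kind)
  expected <- c(geometry$det_bins, geometry$n_proj)
  if (!identical(dim(values), as.integer(expected)))
    stop("sinogram values must be ", paste(expected, collapse = " x "))
  if (any(values < 0)) stop("sinogram values must be nonnegative")
  if (kind == "counts" && any(values != round(values)))
    stop("counts sinogram must be integer-valued")
  structure(list(values = values, geometry = geometry, kind = kind,
                 seed = seed, photon_budget = photon_budget),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat("sinogram (", x$kind, "): ",
      paste(dim(x$values), collapse = " x "),
      ", total ", format(sum(x$values), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Add two sinograms binwise
#'
#' Addition is only defined for identical geometries; counts stay counts.
#' @param e1,e2 sinograms.
#' @export
"+.sinogram" <- function(e1, e2) {
  if (!same_geometry(e1$geometry, e2$geometry))
    stop("cannot add sinograms with different geometries")
  kind <- if (e1$kind == "counts" && e2$kind == "counts") "counts" else "expectation"
  sinogram(e1$values + e2$values, e1$geometry, kind = kind)
}

#' Poisson count sampling of an expectation sinogram
#'
#' Independent Poisson draw per bin, reproducible under `seed`.
#'
#' @param expectation a `sinogram` of kind `"expectation"`.
#' @param seed integer seed.
#' @return a `sinogram` of kind `"counts"`.
#' @export
sample_counts <- function(expectation, seed) {
  stopifnot(inherits(expectation, "sinogram"))
  if (expectation$kind != "expectation")
    stop("sample_counts expects an expectation sinogram")
  v <- expectation$values
  if (any(v < 0)) stop("negative expectation bin")
  counts <- with_seed(seed, stats::rpois(length(v), v))
  sinogram(array(as.numeric(counts), dim = dim(v)), expectation$geometry,
           kind = "counts", seed = as.integer(seed))
}
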