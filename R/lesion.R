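#' Lesion specification
#'
#' The simulated lesion is a sphere of `radius_voxels` voxels centred on an
#' edge-midpoint lattice site, given a concentration `tnc_target` times the
#' local normal-tissue concentration measured in a control sphere of
#' `control_radius_voxels` voxels around the same site. The defaults
#' (radius 1 voxel, TNC 8, control radius 3) give a 4-voxel lesion of
#' volume 0.35 cm^3 at 4.42 mm voxels.
#'
#' @param radius_voxels sphere radius in voxel units (> 0), default 1.
#' @param tnc_target tumor-to-normal concentration ratio (> 1), default 8.
#' @param control_radius_voxels control-sphere radius in voxels (must
#'   exceed the lesion radius), default 3.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(radius_voxels = 1, tnc_target = 8,
                        control_radius_voxels = 3L) {
  if (radius_voxels <= 0) stop("radius_voxels must be > 0")
  if (tnc_target <= 1) stop("tnc_target must be > 1")
  if (control_radius_voxels <= radius_voxels)
    stop("control radius must exceed the lesion radius")
  structure(list(radius_voxels = radius_voxels, tnc_target = tnc_target,
                 control_radius_voxels = as.integer(control_radius_voxels)),
            class = "lesion_spec")
}

# Edge-midpoint lattice: candidate sphere centres sit midway between voxel
# centres in x and y and on a voxel centre in z, the unique symmetric
# convention for which a radius-1-voxel sphere contains exactly 4 voxel
# centres (a 2 x 2 x 1 block). A site is indexed by the block origin
# (x0, y0, z0), 0-based; its centre in index units is (x0+0.5, y0+0.5, z0).

site_center_index <- function(origin) {
  cbind(origin[, 1] + 0.5, origin[, 2] + 0.5, origin[, 3])
}

# all lattice sites whose control sphere lies fully inside the liver mask
eligible_sites <- function(liver_mask, grid, spec) {
  d <- grid$dims
  rc <- spec$control_radius_voxels
  off <- expand.grid(x = -(rc + 1):(rc + 1), y = -(rc + 1):(rc + 1),
                     z = -rc:rc)
  keep <- sqrt((off$x - 0.5)^2 + (off$y - 0.5)^2 + off$z^2) <= rc
  off <- as.matrix(off[keep, , drop = FALSE])
  # site (x0,y0,z0) eligible iff every control voxel (x0+ox, y0+oy, z0+oz)
  # is inside the grid and the liver mask
  elig <- array(TRUE, dim = d)
  for (r in seq_len(nrow(off))) {
    o <- off[r, ]
    shifted <- shift_mask(liver_mask, o)
    elig <- elig & shifted
  }
  which(elig) # linear indices of eligible block origins (1-based)
}

# mask value at (i + o), FALSE outside the grid
shift_mask <- function(mask, o) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  sx <- seq_len(d[1]) + o[1]; kx <- sx >= 1 & sx <= d[1]
  sy <- seq_len(d[2]) + o[2]; ky <- sy >= 1 & sy <= d[2]
  sz <- seq_len(d[3]) + o[3]; kz <- sz >= 1 & sz <= d[3]
  out[which(kx), which(ky), which(kz)] <-
    mask[sx[kx], sy[ky], sz[kz], drop = FALSE]
  out
}

#' Sample a lesion position in the liver
#'
#' Draws uniformly over the eligible edge-midpoint lattice sites — those
#' whose control sphere lies fully inside the liver — and returns the
#' world-mm centre. Reproducible under `seed`.
#'
#' @param liver_mask logical 3-D array.
#' @param grid the [voxel_grid()].
#' @param spec a [lesion_spec()].
#' @param seed integer seed.
#' @param n number of independent draws (with replacement), default 1.
#' @return length-3 world mm coordinates of the sphere centre (`n = 1`),
#'   or an `n` x 3 matrix.
#' @export
sample_position <- function(liver_mask, grid, spec = lesion_spec(), seed = 1,
                            n = 1L) {
  if (!any(liver_mask)) stop("liver mask is empty")
  sites <- eligible_sites(liver_mask, grid, spec)
  if (length(sites) == 0)
    stop("no eligible lesion site: the liver is too small for the control ",
         "radius; enlarge the liver or reduce control_radius_voxels")
  picks <- with_seed(seed, sites[sample.int(length(sites), n, replace = TRUE)])
  origin <- unflat_index(grid, picks)
  center_idx <- site_center_index(origin)
  out <- sweep(sweep(center_idx + 0.5, 2, grid$voxel_size, "*"),
               2, grid$origin, "+")
  if (n == 1L) out[1, ] else out
}

#' Voxelize a sphere on the grid
#'
#' Returns all voxels whose centres lie within `radius_voxels * voxel_size`
#' of the centre. For radius 1 and an edge-midpoint centre this is exactly
#' the 2 x 2 x 1 block of 4 voxels.
#'
#' @param center_mm world mm sphere centre.
#' @param radius_voxels sphere radius in voxel units.
#' @param grid the [voxel_grid()].
#' @return integer matrix (n x 3) of 0-based voxel indices.
#' @export
voxelize_sphere <- function(center_mm, radius_voxels, grid) {
  if (radius_voxels <= 0) stop("radius must be > 0")
  cidx <- (center_mm - grid$origin) / grid$voxel_size - 0.5
  r <- radius_voxels
  lo <- floor(cidx - r); hi <- ceiling(cidx + r)
  cand <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                z = lo[3]:hi[3]))
  d2 <- (cand[, 1] - cidx[1])^2 + (cand[, 2] - cidx[2])^2 +
        (cand[, 3] - cidx[3])^2
  vox <- cand[d2 <= r^2 + 1e-12, , drop = FALSE]
  if (nrow(vox) == 0)
    stop("invalid lesion spec: radius ", radius_voxels,
         " voxels contains no voxel centres at this position")
  if (any(vox < 0) || any(sweep(vox, 2, grid$dims, ">=")))
    stop("sphere extends outside the grid")
  storage.mode(vox) <- "integer"
  dimnames(vox) <- list(NULL, c("x", "y", "z"))
  vox
}

#' Local normal-tissue concentration in the control sphere
#'
#' Mean activity over voxels whose centres lie within
#' `control_radius_voxels * voxel_size` of the centre, excluding the
#' prospective tumor voxels (so the measurement is not self-contaminated).
#'
#' @param activity 3-D activity array (Bq/ml).
#' @param grid the [voxel_grid()].
#' @param center_mm world mm centre.
#' @param control_radius_voxels control radius in voxels.
#' @param exclude optional n x 3 matrix of 0-based voxel indices to exclude
#'   (the tumor voxels).
#' @return mean concentration, Bq/ml.
#' @export
control_voi_mean <- function(activity, grid, center_mm,
                             control_radius_voxels = 3,
                             exclude = NULL) {
  vox <- voxelize_sphere(center_mm, control_radius_voxels, grid)
  lin <- flat_index(grid, vox)
  if (!is.null(exclude)) lin <- setdiff(lin, flat_index(grid, exclude))
  mean(activity[lin])
}

#' Build the lesion-only activity map
#'
#' Computes the local concentration in the control sphere, then sets the
#' tumor voxels to `tnc_target` times that concentration and everything
#' else to zero. The lesion is purely additive: it is later summed with
#' the patient raw data, so the normal-tissue background underneath
#' remains in place.
#'
#' @param case a `phantom_case`.
#' @param center_mm world mm lesion centre (from [sample_position()]).
#' @param spec a [lesion_spec()].
#' @return list with `activity` (lesion-only 3-D array) and `truth`
#'   (class `lesion_truth`: case id, centre, tumor voxels, local and
#'   inserted concentration).
#' @export
make_lesion_source <- function(case, center_mm, spec = lesion_spec()) {
  grid <- case$grid
  vox <- voxelize_sphere(center_mm, spec$radius_voxels, grid)
  local_c <- control_voi_mean(case$activity, grid, center_mm,
                              spec$control_radius_voxels, exclude = vox)
  if (local_c <= 0)
    stop("local concentration is not positive: lesion undefined in a cold region")
  inserted <- spec$tnc_target * local_c
  act <- array(0, dim = grid$dims)
  act[flat_index(grid, vox)] <- inserted
  truth <- structure(list(case_id = case$case_id, center_mm = center_mm,
                          voxels = vox, local_concentration = local_c,
                          inserted_concentration = inserted,
                          tnc_target = spec$tnc_target),
                     class = "lesion_truth")
  list(activity = act, truth = truth)
}

#' @export
print.lesion_truth <- function(x, ...) {
  cat("lesion_truth ", x$case_id, ": centre (",
      paste(round(x$center_mm, 1), collapse = ", "), ") mm, ",
      nrow(x$voxels), " voxels, local ", round(x$local_concentration),
      " Bq/ml, inserted ", round(x$inserted_concentration),
      " Bq/ml (TNC ", x$tnc_target, ")\n", sep = "")
  invisible(x)
}

#' Insert a simulated lesion into patient raw data
#'
#' Simulates the lesion-only sinogram by Monte Carlo photon transport of
#' the lesion source through the patient attenuation maps, samples Poisson
#' counts from it, and adds it binwise to the patient counts. The patient
#' sinogram is not modified.
#'
#' @param patient_sino patient counts [sinogram()].
#' @param case the `phantom_case` (attenuation maps).
#' @param lesion_activity lesion-only activity array from
#'   [make_lesion_source()].
#' @param geom the shared [system_geometry()].
#' @param n_photons Monte Carlo photon budget for the lesion simulation.
#' @param seed integer seed (transport and Poisson draw derive from it).
#' @return a counts [sinogram()] containing patient plus lesion.
#' @export
insert_lesion <- function(patient_sino, case, lesion_activity, geom,
                          n_photons = 2e5, seed = 1) {
  stopifnot(inherits(patient_sino, "sinogram"))
  if (!same_geometry(patient_sino$geometry, geom))
    stop("geometry mismatch between patient sinogram and lesion simulation")
  if (all(lesion_activity == 0)) return(patient_sino)
  seeds <- derive_seeds(seed, 2)
  expect <- mc_forward(lesion_activity, case$mu_171, case$mu_245, geom,
                       case$grid, n_photons = n_photons, seed = seeds[1],
                       scatter = TRUE, mode = "forced", cdr = TRUE)
  lesion_counts <- sample_counts(expect, seeds[2])
  patient_sino + lesion_counts
}
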