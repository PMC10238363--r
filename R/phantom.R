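#' Phantom configuration
#'
#' Describes the synthetic abdominal phantom: an elliptical-cylinder body,
#' an ellipsoidal liver with spatially correlated uptake heterogeneity, two
#' ellipsoidal kidneys, and a bone-like spine insert in the pseudo-CT. All
#' positions and semi-axes are world mm; concentrations are Bq/ml.
#'
#' The liver heterogeneity is a multiplicative log-normal random field with
#' mean 1: a Gaussian random field with autocorrelation
#' `exp(-d^2 / (2 * corr_length_mm^2))` is exponentiated and scaled so the
#' voxelwise coefficient of variation equals `cv`. This supplies the
#' "anatomical noise" that can mask a lesion placed in a low-uptake pocket.
#'
#' Default concentrations emulate an In-111 octreotide distribution one day
#' post injection (high kidney uptake, moderate nonuniform liver uptake, low
#' background); with the default geometry the total activity in the field of
#' view is about 120 MBq, inside the 110-220 MBq clinical range.
#'
#' @param dims grid dimensions, default desk profile `c(64, 64, 48)`; the
#'   clinical profile uses `c(128, 128, 128)`.
#' @param voxel_size voxel size in mm, default 4.42.
#' @param body_semi_mm semi-axes (x, y) of the elliptical body cylinder.
#' @param liver_center_mm,liver_semi_mm liver ellipsoid pose.
#' @param kidney_centers_mm 2 x 3 matrix of kidney centres.
#' @param kidney_semi_mm kidney ellipsoid semi-axes (shared).
#' @param conc_background,conc_liver,conc_kidney mean concentrations, Bq/ml.
#' @param liver_cv coefficient of variation of the liver heterogeneity
#'   field (0 disables it), default 0.3.
#' @param corr_length_mm correlation length of the heterogeneity field in
#'   mm, default 15.
#' @param activity_scale global multiplier on all concentrations, default 1;
#'   total activity scales linearly (and exactly) with it.
#' @param hu_soft,hu_bone pseudo-CT Hounsfield values of soft tissue and the
#'   spine insert.
#' @param spine_center_mm,spine_radius_mm spine insert (circular cylinder).
#' @param mu_water,mu_bone named numeric vectors giving the linear
#'   attenuation coefficient (1/mm) of water and cortical-bone-like material
#'   at the photopeak energies "171" and "245" keV.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(64L, 64L, 48L),
                           voxel_size = 4.42,
                           body_semi_mm = c(130, 95),
                           liver_center_mm = c(-45, -20, 20),
                           liver_semi_mm = c(62, 48, 52),
                           kidney_centers_mm = rbind(c(-55, 30, -40),
                                                     c(55, 30, -40)),
                           kidney_semi_mm = c(24, 18, 40),
                           conc_background = 10000,
                           conc_liver = 45000,
                           conc_kidney = 120000,
                           liver_cv = 0.3,
                           corr_length_mm = 15,
                           activity_scale = 1,
                           hu_soft = 40,
                           hu_bone = 700,
                           spine_center_mm = c(0, 60, 0),
                           spine_radius_mm = 15,
                           mu_water = c("171" = 0.0144, "245" = 0.0127),
                           mu_bone = c("171" = 0.0264, "245" = 0.0229)) {
  conc <- c(conc_background, conc_liver, conc_kidney)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("organ concentrations must be nonnegative finite Bq/ml")
  if (liver_cv < 0) stop("liver_cv must be >= 0")
  if (corr_length_mm <= 0) stop("corr_length_mm must be > 0")
  if (activity_scale < 0) stop("activity_scale must be >= 0")
  structure(list(
    dims = as.integer(dims), voxel_size = voxel_size,
    body_semi_mm = body_semi_mm,
    liver_center_mm = liver_center_mm, liver_semi_mm = liver_semi_mm,
    kidney_centers_mm = kidney_centers_mm, kidney_semi_mm = kidney_semi_mm,
    conc_background = conc_background, conc_liver = conc_liver,
    conc_kidney = conc_kidney,
    liver_cv = liver_cv, corr_length_mm = corr_length_mm,
    activity_scale = activity_scale,
    hu_soft = hu_soft, hu_bone = hu_bone,
    spine_center_mm = spine_center_mm, spine_radius_mm = spine_radius_mm,
    mu_water = mu_water, mu_bone = mu_bone
  ), class = "phantom_config")
}

# Evaluate seeded code with the global RNG state restored afterwards, so
# generators are reproducible without clobbering the caller's stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# world-coordinate arrays of voxel centres, one value per voxel per axis
grid_coords <- function(grid) {
  d <- grid$dims
  list(
    x = grid$origin[1] + (seq_len(d[1]) - 0.5) * grid$voxel_size,
    y = grid$origin[2] + (seq_len(d[2]) - 0.5) * grid$voxel_size,
    z = grid$origin[3] + (seq_len(d[3]) - 0.5) * grid$voxel_size
  )
}

ellipsoid_mask <- function(grid, center, semi) {
  co <- grid_coords(grid)
  d <- grid$dims
  fx <- ((co$x - center[1]) / semi[1])^2
  fy <- ((co$y - center[2]) / semi[2])^2
  fz <- ((co$z - center[3]) / semi[3])^2
  array(outer(outer(fx, fy, "+"), fz, "+") <= 1, dim = d)
}

# Spatially correlated unit-variance Gaussian field via circular FFT
# convolution of white noise with a Gaussian kernel. Kernel sd is chosen so
# the field autocorrelation is exp(-d^2 / (2 L^2)) with L = corr_length_mm.
correlated_gaussian_field <- function(grid, corr_length_mm) {
  d <- grid$dims
  s_vox <- (corr_length_mm / sqrt(2)) / grid$voxel_size
  w <- array(stats::rnorm(prod(d)), dim = d)
  if (s_vox < 1e-6) return(w)
  kern1 <- function(n) {
    # periodic distance to 0 along an axis of length n
    i <- c(0:(n %/% 2), if (n > 1) -((n - (n %/% 2 + 1)):1))
    k <- exp(-i^2 / (2 * s_vox^2))
    k
  }
  kx <- kern1(d[1]); ky <- kern1(d[2]); kz <- kern1(d[3])
  kernel <- outer(outer(kx, ky), kz)
  norm2 <- sum(kernel^2)
  fw <- stats::fft(w)
  fk <- stats::fft(kernel)
  sm <- Re(stats::fft(fw * fk, inverse = TRUE)) / prod(d)
  sm / sqrt(norm2)
}

#' Generate one synthetic phantom case
#'
#' Builds the activity map (Bq/ml), pseudo-CT and attenuation maps at 171
#' and 245 keV, and organ masks, on the configured grid. Regeneration from
#' the same `(config, seed)` is bit-identical.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed for the liver heterogeneity field.
#' @param case_id optional case identifier string.
#' @return an object of class `phantom_case` with elements `case_id`,
#'   `grid`, `activity` (3-D array, Bq/ml), `total_activity_mbq`, `hu`,
#'   `mu_171`, `mu_245` (1/mm), `masks` (list of logical arrays `liver`,
#'   `kidneys`, `body`), `seed`, `config`.
#' @export
generate_phantom <- function(config, seed, case_id = sprintf("case_%06d", seed)) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- voxel_grid(config$dims, config$voxel_size)
  fov_half <- grid$dims * grid$voxel_size / 2

  check_fit <- function(name, center, semi3) {
    if (any(abs(center) + semi3 > fov_half + 1e-9))
      stop("configuration error: organ '", name,
           "' does not fit inside the grid field of view")
  }
  check_fit("body", c(0, 0, 0),
            c(config$body_semi_mm, fov_half[3]) * c(1, 1, 0.999))
  check_fit("liver", config$liver_center_mm, config$liver_semi_mm)
  check_fit("kidney_right", config$kidney_centers_mm[1, ], config$kidney_semi_mm)
  check_fit("kidney_left", config$kidney_centers_mm[2, ], config$kidney_semi_mm)

  co <- grid_coords(grid)
  body2d <- outer((co$x / config$body_semi_mm[1])^2,
                  (co$y / config$body_semi_mm[2])^2, "+") <= 1
  body <- array(rep(body2d, grid$dims[3]), dim = grid$dims)
  liver <- ellipsoid_mask(grid, config$liver_center_mm, config$liver_semi_mm) & body
  kid <- (ellipsoid_mask(grid, config$kidney_centers_mm[1, ], config$kidney_semi_mm) |
          ellipsoid_mask(grid, config$kidney_centers_mm[2, ], config$kidney_semi_mm)) &
         body & !liver

  if (sum(liver) < 500)
    stop("configuration error: organ 'liver' has fewer than 500 voxels")

  field <- if (config$liver_cv > 0) {
    g <- with_seed(seed, correlated_gaussian_field(grid, config$corr_length_mm))
    sig <- sqrt(log(1 + config$liver_cv^2))
    exp(sig * g - sig^2 / 2)
  } else {
    array(1, dim = grid$dims)
  }

  act <- array(0, dim = grid$dims)
  act[body] <- config$conc_background
  act[liver] <- config$conc_liver * field[liver]
  act[kid] <- config$conc_kidney
  act <- act * config$activity_scale

  # pseudo-CT: soft tissue body, bone-like spine cylinder, air outside
  hu <- array(-1000, dim = grid$dims)
  hu[body] <- config$hu_soft
  spine2d <- outer((co$x - config$spine_center_mm[1])^2,
                   (co$y - config$spine_center_mm[2])^2, "+") <=
    config$spine_radius_mm^2
  spine <- array(rep(spine2d, grid$dims[3]), dim = grid$dims) & body
  hu[spine] <- config$hu_bone

  mu_171 <- hu_to_mu(hu, 171, config)
  mu_245 <- hu_to_mu(hu, 245, config)

  structure(list(
    case_id = case_id, grid = grid,
    activity = act,
    total_activity_mbq = sum(act) * voxel_volume_ml(grid) / 1e6,
    hu = hu, mu_171 = mu_171, mu_245 = mu_245,
    masks = list(liver = liver, kidneys = kid, body = body),
    seed = as.integer(seed), config = config
  ), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("phantom_case ", x$case_id, ": ",
      paste(x$grid$dims, collapse = "x"), " @ ", x$grid$voxel_size, " mm, ",
      sprintf("%.1f MBq total, liver %d voxels\n",
              x$total_activity_mbq, sum(x$masks$liver)), sep = "")
  invisible(x)
}

#' Convert Hounsfield units to linear attenuation coefficients
#'
#' Piecewise-linear (bilinear) HU to mu mapping with breakpoints at air
#' (HU = -1000, mu = 0), water (HU = 0, mu = `mu_water[energy]`) and
#' bone (HU = 1000, mu = `mu_bone[energy]`); linear continuation above
#' 1000 HU, clamped at 0 below -1000 HU. Monotone nondecreasing in HU.
#'
#' @param hu numeric array or vector of Hounsfield values.
#' @param energy photopeak energy in keV; one of 171 or 245.
#' @param config a [phantom_config()] supplying `mu_water` and `mu_bone`.
#' @return mu values (1/mm) with the same shape as `hu`.
#' @export
hu_to_mu <- function(hu, energy, config = phantom_config()) {
  key <- as.character(as.integer(energy))
  if (!key %in% names(config$mu_water))
    stop("unsupported energy ", energy, " keV; supported photopeaks: ",
         paste(names(config$mu_water), collapse = ", "))
  if (any(!is.finite(hu))) stop("hu must be finite")
  muw <- config$mu_water[[key]]
  mub <- config$mu_bone[[key]]
  mu <- ifelse(hu <= 0,
               muw * (1 + pmax(hu, -1000) / 1000),
               muw + hu * (mub - muw) / 1000)
  mu[mu < 0] <- 0
  if (is.array(hu)) mu <- array(mu, dim = dim(hu))
  mu
}

#' Generate a cohort of phantom cases
#'
#' Per-case seeds are derived deterministically from the master seed, so the
#' cohort is reproducible and cases are pairwise distinct.
#'
#' @param n number of cases (default 37, the emulated study cohort).
#' @param config a [phantom_config()].
#' @param seed master integer seed.
#' @return list of `phantom_case` objects with sequential case ids.
#' @export
generate_cohort <- function(n = 37, config = phantom_config(), seed = 1) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer")
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(i)
    generate_phantom(config, seeds[i], case_id = sprintf("case_%03d", i)))
}

# deterministic stream of distinct 32-bit seeds from a master seed
derive_seeds <- function(seed, n, salt = 0L) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647  # minimal standard LCG step
    out[i] <- s
  }
  as.integer((out + as.numeric(salt)) %% 2147483647)
}
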