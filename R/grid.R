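#' Voxel grid geometry
#'
#' A `voxel_grid` fixes the sampling geometry shared by all volumes in a
#' case: grid dimensions, isotropic voxel size in mm, and the world-space
#' offset of the first voxel. The convention used throughout the package is
#' 0-based voxel indices with voxel-centre world coordinates: voxel index
#' `i` (0-based, per axis) has its centre at `origin + (i + 0.5) * voxel_size`.
#' Axes are (x, y, z) = (right to left, anterior to posterior, inferior to
#' superior).
#'
#' @param dims integer vector of length 3, grid dimensions `(nx, ny, nz)`;
#'   each must be at least 16.
#' @param voxel_size voxel edge length in mm (isotropic), default 4.42.
#' @param origin world-space mm offset of the corner of voxel (0,0,0);
#'   default centres the grid on the world origin.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, voxel_size = 4.42, origin = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(!is.finite(dims)))
    stop("dims must be three finite integers")
  if (any(dims < 16L))
    stop("grid too small: all dims must be >= 16, got (",
         paste(dims, collapse = ", "), ")")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number (mm)")
  if (is.null(origin)) origin <- -dims * voxel_size / 2
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers (mm)")
  structure(list(dims = dims, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid: ", paste(x$dims, collapse = " x "),
      " voxels @ ", x$voxel_size, " mm\n", sep = "")
  invisible(x)
}

#' World coordinates of voxel centres
#'
#' Converts 0-based voxel indices to world mm coordinates of the voxel
#' centres under the package convention.
#'
#' @param grid a [voxel_grid()].
#' @param idx integer matrix (n x 3) of 0-based voxel indices, or a length-3
#'   vector.
#' @return numeric matrix (n x 3) of world mm coordinates.
#' @export
voxel_center <- function(grid, idx) {
  stopifnot(inherits(grid, "voxel_grid"))
  idx <- rbind_idx(idx)
  sweep(sweep(idx + 0.5, 2, grid$voxel_size, "*"), 2, grid$origin, "+")
}

#' Voxel index containing a world point
#'
#' @param grid a [voxel_grid()].
#' @param xyz numeric matrix (n x 3) or length-3 vector of world mm
#'   coordinates.
#' @return integer matrix (n x 3) of 0-based voxel indices (floored).
#' @export
world_to_index <- function(grid, xyz) {
  stopifnot(inherits(grid, "voxel_grid"))
  xyz <- rbind_idx(xyz)
  idx <- floor(sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$voxel_size, "/"))
  storage.mode(idx) <- "integer"
  idx
}

rbind_idx <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != 3L) stop("expected 3 columns (x, y, z)")
  x
}

#' @keywords internal
same_grid <- function(a, b, tol = 1e-9) {
  identical(a$dims, b$dims) &&
    abs(a$voxel_size - b$voxel_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' Voxel volume in millilitres
#' @param grid a [voxel_grid()].
#' @return voxel volume in ml (cm^3).
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  grid$voxel_size^3 / 1000
}

# linear (1-based R) index from an n x 3 matrix of 0-based voxel indices
flat_index <- function(grid, idx) {
  idx <- rbind_idx(idx)
  d <- grid$dims
  if (any(idx < 0L) || any(sweep(idx, 2, d, ">=")))
    stop("voxel index outside grid")
  1L + idx[, 1L] + d[1L] * (idx[, 2L] + d[2L] * idx[, 3L])
}

# inverse of flat_index: n x 3 matrix of 0-based indices
unflat_index <- function(grid, lin) {
  d <- grid$dims
  lin0 <- as.integer(lin) - 1L
  x <- lin0 %% d[1L]
  y <- (lin0 %/% d[1L]) %% d[2L]
  z <- lin0 %/% (d[1L] * d[2L])
  cbind(x = x, y = y, z = z)
}
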