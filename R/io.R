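#' Volume I/O as NIfTI-1
#'
#' Volumes (activity, attenuation, reconstructions) are written as NIfTI-1
#' with the voxel size in the pixdim header; masks should be written with
#' `datatype = "uint8"`.
#'
#' @param volume 3-D numeric or logical array.
#' @param grid the [voxel_grid()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype, e.g. `"double"` (default) or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, grid, path, datatype = "double") {
  a <- volume * 1
  attr(a, "pixdim") <- rep(grid$voxel_size, 3)
  img <- RNifti::asNifti(a, datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @return `read_volume`: a list with `values` (3-D array) and `grid`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1]
  arr <- array(as.numeric(img), dim = dim(img))
  list(values = arr, grid = voxel_grid(dim(img), voxel_size = vs))
}

#' Sinogram I/O
#'
#' The projection array is stored as an RDS container next to a JSON
#' sidecar holding the acquisition geometry, so raw data remain
#' self-describing.
#'
#' @param sino a [sinogram()].
#' @param path output path (`.rds`; the sidecar adds `.json`).
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  saveRDS(sino$values, path)
  g <- sino$geometry
  jsonlite::write_json(
    list(n_proj = g$n_proj, angles_deg = g$angles_deg,
         det_bins = g$det_bins, bin_size = g$bin_size,
         orbit_radius_mm = g$orbit_radius_mm,
         time_per_proj_s = g$time_per_proj_s,
         energy_windows = lapply(g$energy_windows, as.list),
         sensitivity = g$sensitivity, kind = sino$kind,
         seed = sino$seed, photon_budget = sino$photon_budget),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @param geom a [system_geometry()] matching the stored sidecar.
#' @export
read_sinogram <- function(path, geom) {
  values <- readRDS(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sinogram(values, geom, kind = side$kind,
           seed = if (is.null(side$seed)) NA_integer_ else side$seed)
}

#' Read an observer-assessment table
#'
#' Delimited text with columns `case_id`, `arm`, `called` (logical or
#' 0/1), `confidence` (1-3), and `x_mm`, `y_mm`, `z_mm` (empty or NA when
#' no lesion was called).
#'
#' @param path CSV file path.
#' @return validated data frame ready for [summarize_assessments()].
#' @export
read_assessments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "arm", "called", "confidence", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("assessment table is missing columns: ", paste(miss, collapse = ", "))
  df$called <- as.logical(df$called)
  if (any(df$called & (is.na(df$x_mm) | is.na(df$y_mm) | is.na(df$z_mm))))
    stop("positive calls must carry coordinates")
  if (any(!df$confidence %in% 1:3)) stop("confidence must be 1, 2 or 3")
  df
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experiment_config()]; nested
#' `phantom:` and `acquisition:` blocks override [phantom_config()] and
#' [system_geometry()] fields.
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- do.call(phantom_config, y$phantom %||% list())
  geom <- if (is.null(y$acquisition)) NULL
          else do.call(system_geometry, y$acquisition)
  args <- y[setdiff(names(y), c("phantom", "acquisition"))]
  do.call(experiment_config, c(args, list(phantom = ph, geom = geom)))
}
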