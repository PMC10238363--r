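#' Experiment configuration
#'
#' Bundles every stage of the study design: cohort size and positive split,
#' phantom and acquisition settings, lesion specification, per-arm
#' reconstruction settings, and evaluation options. Three profiles are
#' provided: `"desk"` (64 x 64 x 48 grid, 60 projections, reduced photon
#' budgets; the default, sized for interactive work), `"compact"`
#' (48 x 48 x 32 with proportionally scaled organs, 40 projections,
#' further reduced budgets; sized so cohort-level studies run in minutes)
#' and `"clinical"` (128 x 128 x 128, 120 projections, full budgets).
#'
#' @param cohort_size number of cases, default 37.
#' @param positives number of cases receiving a lesion, default 26.
#' @param profile `"desk"` or `"clinical"`.
#' @param phantom a [phantom_config()]; default per profile.
#' @param geom a [system_geometry()]; default per profile.
#' @param lesion a [lesion_spec()].
#' @param photons_acquire Monte Carlo photon budget for the patient
#'   acquisition simulation.
#' @param photons_lesion photon budget for the lesion-only simulation.
#' @param photons_per_forward photon budget per OSEM forward call (MC arm).
#' @param match_tolerance_mm coordinate-match tolerance for scoring,
#'   default 8.84 mm (2 voxels).
#' @param snr_samples number of random liver VOIs for the SNR, default 20.
#' @param observer_threshold z-score threshold of the scripted readout
#'   observer, default 3.5.
#' @param observer_conf_breaks z-score breaks separating confidence 1/2/3.
#' @param detectable_fraction a lesion is flagged detectable when its local
#'   concentration is at least this fraction of the mean liver
#'   concentration (the low-uptake-pocket "disappearance" rule).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(cohort_size = 37L, positives = 26L,
                              profile = c("desk", "compact", "clinical"),
                              phantom = NULL, geom = NULL,
                              lesion = lesion_spec(),
                              photons_acquire = NULL,
                              photons_lesion = 2e5,
                              photons_per_forward = NULL,
                              match_tolerance_mm = 8.84,
                              snr_samples = 20L,
                              observer_threshold = 3.5,
                              observer_conf_breaks = c(4.25, 5.0),
                              detectable_fraction = 0.7) {
  profile <- match.arg(profile)
  cohort_size <- as.integer(cohort_size); positives <- as.integer(positives)
  if (positives > cohort_size) stop("positives must not exceed cohort_size")
  if (is.null(phantom))
    phantom <- switch(profile,
      desk = phantom_config(),
      compact = phantom_config(dims = c(48L, 48L, 32L),
                               body_semi_mm = c(85, 62),
                               liver_center_mm = c(-28, -12, 8),
                               liver_semi_mm = c(40, 32, 32),
                               kidney_centers_mm = rbind(c(-34, 20, -24),
                                                         c(34, 20, -24)),
                               kidney_semi_mm = c(15, 11, 20),
                               spine_center_mm = c(0, 40, 0),
                               spine_radius_mm = 10),
      clinical = phantom_config(dims = c(128L, 128L, 128L)))
  if (is.null(geom)) {
    nb <- phantom$dims[c(1, 3)]
    np <- switch(profile, desk = 60L, compact = 40L, clinical = 120L)
    orb <- switch(profile, desk = 250, compact = 180, clinical = 300)
    geom <- system_geometry(n_proj = np, det_bins = nb,
                            bin_size = phantom$voxel_size,
                            orbit_radius_mm = orb)
  }
  if (is.null(photons_acquire))
    photons_acquire <- switch(profile, desk = 2e6, compact = 1e6,
                              clinical = 1e7)
  if (is.null(photons_per_forward))
    photons_per_forward <- switch(profile, desk = 5e4, compact = 3e4,
                                  clinical = 2e5)
  if (profile == "compact" && missing(photons_lesion)) photons_lesion <- 1e5
  structure(list(cohort_size = cohort_size, positives = positives,
                 profile = profile, phantom = phantom, geom = geom,
                 lesion = lesion, photons_acquire = photons_acquire,
                 photons_lesion = photons_lesion,
                 photons_per_forward = photons_per_forward,
                 match_tolerance_mm = match_tolerance_mm,
                 snr_samples = as.integer(snr_samples),
                 observer_threshold = observer_threshold,
                 observer_conf_breaks = observer_conf_breaks,
                 detectable_fraction = detectable_fraction),
            class = "experiment_config")
}

# short stable hash of an R object (polynomial rolling hash over its
# serialization, kept within 31 bits)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

#' Scripted readout observer
#'
#' A deterministic stand-in for the human reader, so the evaluation layer
#' is testable without one (it is not a validated model observer). The
#' volume is smoothed with a lesion-sized matched filter, background-
#' subtracted with a broad Gaussian, restricted to the eroded liver, and
#' standardized robustly; the most suspicious site is the arg-max of this
#' z-map. A case is called positive when the peak z exceeds `threshold`
#' (calibrated for a maximum over a few thousand liver voxels), with
#' confidence binned by z, and the call coordinates are the arg-max voxel
#' centre.
#'
#' @param volume reconstructed 3-D array.
#' @param liver_mask logical 3-D array.
#' @param grid the [voxel_grid()].
#' @param threshold z-score call threshold, default 3.5.
#' @param conf_breaks increasing z breaks for confidence 2 and 3.
#' @param bg_sigma_mm background-subtraction Gaussian sigma, default 15 mm.
#' @param matched_sigma_mm matched-filter Gaussian sigma, default 4 mm
#'   (lesion-sized).
#' @return list with `called`, `confidence`, `coords_mm`, `z` (peak
#'   z-score).
#' @export
readout_observer <- function(volume, liver_mask, grid, threshold = 3.5,
                             conf_breaks = c(4.25, 5.0), bg_sigma_mm = 15,
                             matched_sigma_mm = 4) {
  sm <- gaussian_lp(volume, matched_sigma_mm, grid$voxel_size)
  bg <- gaussian_lp(volume, bg_sigma_mm, grid$voxel_size)
  dmap <- sm - bg
  core <- erode_mask(liver_mask)
  if (!any(core)) core <- liver_mask
  dv <- dmap[core]
  sc <- stats::mad(dv)
  if (sc == 0) sc <- stats::sd(dv)
  if (is.na(sc) || sc == 0) sc <- 1
  z <- (dmap - stats::median(dv)) / sc
  z[!core] <- -Inf
  peak <- which.max(z)
  zmax <- z[peak]
  called <- is.finite(zmax) && zmax > threshold
  # confidence grows with distance from the call threshold on either side
  margin <- abs(zmax - threshold)
  conf <- min(3L, 1L + sum(margin > conf_breaks - threshold))
  coords <- voxel_center(grid, unflat_index(grid, peak))[1, ]
  list(called = called, confidence = conf,
       coords_mm = if (called) coords else NULL, z = zmax)
}

erode_mask <- function(mask) {
  out <- mask
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    out <- out & shift_mask(mask, o)
  out
}

#' Run the full simulated study
#'
#' Generates a cohort of phantoms, simulates the acquisition of each,
#' inserts lesions into the positive cases, reconstructs every case with
#' the three arms (the same counts sinogram feeds all arms), extracts
#' quantitative metrics and scripted-observer assessments, and summarizes
#' scenarios AL and DL. Deterministic given `(config, seed)`.
#'
#' @param config an [experiment_config()].
#' @param seed master integer seed.
#' @param out_dir optional output directory; when given, volumes are
#'   written as NIfTI with a JSON provenance sidecar and tables as CSV.
#' @return a `results_bundle` list: `truths`, `metrics`, `assessments`
#'   (data frames), `summaries` (AL/DL confusion summaries), `auc`
#'   (per arm and scenario), `manifest` (case ids, seeds, config hash,
#'   volume count).
#' @export
run_experiment <- function(config = experiment_config(), seed = 1,
                           out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  geom <- config$geom
  n <- config$cohort_size
  arms <- c("fAC_OSEM", "fMC_OSEM", "MC_OSEM")
  seeds <- derive_seeds(seed, 6L * n + 1L)
  pos_idx <- with_seed(seeds[6L * n + 1L],
                       sort(sample.int(n, config$positives)))
  cohort <- generate_cohort(n, config$phantom, seed)

  truths <- metrics <- assessments <- list()
  vol_count <- 0L
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  for (i in seq_len(n)) {
    case <- cohort[[i]]
    grid <- case$grid
    s <- seeds[(6L * (i - 1L) + 1L):(6L * i)]
    expect <- mc_forward(case$activity, case$mu_171, case$mu_245, geom, grid,
                         n_photons = config$photons_acquire, seed = s[1])
    counts <- sample_counts(expect, s[2])
    positive <- i %in% pos_idx
    truth_row <- data.frame(case_id = case$case_id, positive = positive,
                            x_mm = NA_real_, y_mm = NA_real_, z_mm = NA_real_,
                            local_concentration = NA_real_,
                            inserted_concentration = NA_real_,
                            detectable = NA)
    lesion_truth <- NULL
    if (positive) {
      center <- sample_position(case$masks$liver, grid, config$lesion, s[3])
      src <- make_lesion_source(case, center, config$lesion)
      lesion_truth <- src$truth
      counts <- insert_lesion(counts, case, src$activity, geom,
                              n_photons = config$photons_lesion, seed = s[4])
      liver_mean <- mean(case$activity[case$masks$liver])
      truth_row[, c("x_mm", "y_mm", "z_mm")] <- as.list(center)
      truth_row$local_concentration <- lesion_truth$local_concentration
      truth_row$inserted_concentration <- lesion_truth$inserted_concentration
      truth_row$detectable <-
        lesion_truth$local_concentration >=
        config$detectable_fraction * liver_mean
    }
    truths[[i]] <- truth_row

    rec_fac <- reconstruct_arm(counts, case, "fAC_OSEM", geom, seed = s[5])
    rec_mc <- reconstruct_arm(
      counts, case, "MC_OSEM", geom, seed = s[6],
      config = osem_config(n_iter = 5L, n_subsets = 10L, floor_frac = 0.02,
                           photons_per_forward = config$photons_per_forward))
    rec_fmc <- rec_mc
    rec_fmc$values <- gaussian_lp(rec_mc$values, 3, grid$voxel_size)
    rec_fmc$arm <- "fMC_OSEM"
    rec_fmc$filter <- "gaussian(sigma=3 mm)"
    recs <- list(fAC_OSEM = rec_fac, fMC_OSEM = rec_fmc, MC_OSEM = rec_mc)

    for (a in arms) {
      rec <- recs[[a]]
      vol_count <- vol_count + 1L
      if (!is.null(out_dir)) {
        vp <- file.path(out_dir, sprintf("%s_%s.nii", case$case_id, a))
        write_volume(rec$values, grid, vp)
        jsonlite::write_json(
          list(case_id = case$case_id, arm = a, filter = rec$filter,
               n_iter = rec$config$n_iter, n_subsets = rec$config$n_subsets,
               seed = seed),
          paste0(vp, ".json"), auto_unbox = TRUE)
      }
      tnc_v <- snr_v <- NA_real_
      if (positive) {
        nv <- build_normal_voi(lesion_truth$voxels, grid)
        tnc_v <- tnc_ratio(rec$values, lesion_truth$voxels, nv, grid)
        snr_v <- snr(rec$values, lesion_truth$voxels, case$masks$liver, grid,
                     n_samples = config$snr_samples, seed = s[3])
      }
      metrics[[length(metrics) + 1L]] <-
        data.frame(case_id = case$case_id, arm = a, positive = positive,
                   tnc = tnc_v, snr = snr_v)
      ro <- readout_observer(rec$values, case$masks$liver, grid,
                             threshold = config$observer_threshold,
                             conf_breaks = config$observer_conf_breaks)
      assessments[[length(assessments) + 1L]] <-
        data.frame(case_id = case$case_id, arm = a, called = ro$called,
                   confidence = ro$confidence,
                   x_mm = if (ro$called) ro$coords_mm[1] else NA_real_,
                   y_mm = if (ro$called) ro$coords_mm[2] else NA_real_,
                   z_mm = if (ro$called) ro$coords_mm[3] else NA_real_,
                   z_score = ro$z)
    }
  }

  truths <- do.call(rbind, truths)
  metrics <- do.call(rbind, metrics)
  assessments <- do.call(rbind, assessments)
  summaries <- list(
    AL = summarize_assessments(assessments, truths, "AL",
                               config$match_tolerance_mm),
    DL = summarize_assessments(assessments, truths, "DL",
                               config$match_tolerance_mm))
  auc <- lapply(c(AL = "AL", DL = "DL"), function(sc) {
    tr <- truths
    if (sc == "DL") tr$positive <- tr$positive & tr$detectable
    lapply(stats::setNames(arms, arms), function(a) {
      as_a <- assessments[assessments$arm == a, ]
      lab <- tr$positive[match(as_a$case_id, tr$case_id)]
      r <- rating(as_a$called, as_a$confidence)
      if (length(unique(lab)) < 2) return(NA_real_)
      empirical_auc(r, lab, n_boot = 500, seed = seed)$auc
    })
  })
  manifest <- list(cohort_size = n, positives = config$positives,
                   arms = arms, n_volumes = vol_count,
                   case_ids = truths$case_id, master_seed = seed,
                   config_hash = config_hash(config))
  if (!is.null(out_dir)) {
    utils::write.csv(truths, file.path(out_dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(assessments, file.path(out_dir, "assessments.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  structure(list(truths = truths, metrics = metrics,
                 assessments = assessments, summaries = summaries,
                 auc = auc, manifest = manifest, config = config),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("results_bundle: ", x$manifest$cohort_size, " cases x ",
      length(x$manifest$arms), " arms = ", x$manifest$n_volumes,
      " reconstructions (config ", x$manifest$config_hash, ")\n", sep = "")
  cat("\nScenario AL:\n"); print(x$summaries$AL)
  cat("\nScenario DL:\n"); print(x$summaries$DL)
  invisible(x)
}
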