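# Shared fixtures for the test suite. All are generated in code at test
# time; sizes are chosen so single tests run in seconds.

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# phantom scaled to a 48 x 48 x 32 grid (FOV ~212 x 212 x 141 mm);
# overrides in ... take precedence over the scaled defaults
small_phantom_config <- function(...) {
  args <- list(dims = c(48L, 48L, 32L),
               body_semi_mm = c(85, 62),
               liver_center_mm = c(-28, -12, 8),
               liver_semi_mm = c(40, 32, 32),
               kidney_centers_mm = rbind(c(-34, 20, -24), c(34, 20, -24)),
               kidney_semi_mm = c(15, 11, 20),
               spine_center_mm = c(0, 40, 0), spine_radius_mm = 10)
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

# even smaller phantom (32 x 32 x 16) for pipeline smoke tests
tiny_phantom_config <- function(...) {
  args <- list(dims = c(32L, 32L, 16L),
               body_semi_mm = c(55, 40),
               liver_center_mm = c(-16, -8, 2),
               liver_semi_mm = c(30, 24, 22),
               kidney_centers_mm = rbind(c(-20, 14, -14), c(20, 14, -14)),
               kidney_semi_mm = c(10, 8, 12),
               spine_center_mm = c(0, 26, 0), spine_radius_mm = 7)
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

small_geometry <- function(n_proj = 40L, dims = c(48L, 48L, 32L), ...) {
  system_geometry(n_proj = n_proj, det_bins = dims[c(1, 3)],
                  bin_size = 4.42, orbit_radius_mm = 180, ...)
}

tiny_geometry <- function(n_proj = 20L, ...) {
  system_geometry(n_proj = n_proj, det_bins = c(32L, 16L),
                  bin_size = 4.42, orbit_radius_mm = 120, ...)
}

tiny_experiment_config <- function(cohort_size = 2L, positives = 1L, ...) {
  args <- list(cohort_size = cohort_size, positives = positives,
               phantom = tiny_phantom_config(),
               geom = tiny_geometry(),
               photons_acquire = 2e5, photons_lesion = 5e4,
               photons_per_forward = 5e3)
  do.call(experiment_config, utils::modifyList(args, list(...)))
}

# Observer assessments and truths reproducing the published study
# accounting: 37 cases, 26 with lesions of which 7 are undetectable; the
# per-arm detected-lesion counts are 8 / 11 / 13, the case-level false
# positives on the 11 negatives are 2 / 5 / 4, and the misplaced calls are
# 2 / 5 / 1, distributed over undetectable lesions as 2 / 1 / 0.
study_truths <- function(voxel = 4.42) {
  pos <- data.frame(case_id = sprintf("P%02d", 1:26), positive = TRUE,
                    x_mm = seq(-60, 60, length.out = 26), y_mm = -20,
                    z_mm = 15,
                    detectable = rep(c(TRUE, FALSE), c(19, 7)))
  neg <- data.frame(case_id = sprintf("N%02d", 1:11), positive = FALSE,
                    x_mm = NA_real_, y_mm = NA_real_, z_mm = NA_real_,
                    detectable = NA)
  rbind(pos, neg)
}

study_assessments <- function() {
  truths <- study_truths()
  counts <- list(fAC_OSEM = list(tp = 8, mis_det = 0, mis_hid = 2, fp = 2),
                 fMC_OSEM = list(tp = 11, mis_det = 4, mis_hid = 1, fp = 5),
                 MC_OSEM  = list(tp = 13, mis_det = 1, mis_hid = 0, fp = 4))
  far <- c(200, 200, 200)  # coordinates far from any true lesion centre
  rows <- lapply(names(counts), function(arm) {
    k <- counts[[arm]]
    det <- which(truths$positive & truths$detectable)   # 19 cases
    hid <- which(truths$positive & !truths$detectable)  # 7 cases
    neg <- which(!truths$positive)                      # 11 cases
    df <- data.frame(case_id = truths$case_id, arm = arm, called = FALSE,
                     confidence = 2L, x_mm = NA_real_, y_mm = NA_real_,
                     z_mm = NA_real_)
    tp_cases <- det[seq_len(k$tp)]
    df$called[tp_cases] <- TRUE
    df[tp_cases, c("x_mm", "y_mm", "z_mm")] <-
      truths[tp_cases, c("x_mm", "y_mm", "z_mm")]
    mis_cases <- c(det[k$tp + seq_len(k$mis_det)], hid[seq_len(k$mis_hid)])
    df$called[mis_cases] <- TRUE
    df[mis_cases, c("x_mm", "y_mm", "z_mm")] <-
      matrix(far, length(mis_cases), 3, byrow = TRUE)
    fp_cases <- neg[seq_len(k$fp)]
    df$called[fp_cases] <- TRUE
    df[fp_cases, c("x_mm", "y_mm", "z_mm")] <-
      matrix(far, length(fp_cases), 3, byrow = TRUE)
    df
  })
  do.call(rbind, rows)
}
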