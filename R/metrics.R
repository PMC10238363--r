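#' Normal-tissue VOI surrounding the tumor
#'
#' Deterministic construction of the 34-voxel normal-tissue reference
#' region around the standard 2 x 2 x 1 tumor block: candidate voxels are
#' those at Chebyshev distance exactly 2 from the block (so none is
#' 26-adjacent to any tumor voxel) lying in one of the three orthogonal
#' voxel planes through the block (the transverse plane of the block and
#' its two sagittal / two coronal voxel planes); of these the 34 nearest
#' the sphere centre (Euclidean, lexicographic z-y-x tie-break) are kept.
#' The construction is translation-equivariant.
#'
#' @param tumor_voi integer matrix (4 x 3) of 0-based tumor voxel indices
#'   (a 2 x 2 x 1 block).
#' @param grid the [voxel_grid()].
#' @return integer matrix (34 x 3) of 0-based voxel indices.
#' @export
build_normal_voi <- function(tumor_voi, grid) {
  tumor_voi <- rbind_idx(tumor_voi)
  if (nrow(tumor_voi) != 4L)
    stop("tumor VOI must be the standard 4-voxel block")
  x0 <- min(tumor_voi[, 1]); y0 <- min(tumor_voi[, 2]); z0 <- min(tumor_voi[, 3])
  block_ok <- setequal(
    apply(tumor_voi, 1, paste, collapse = ","),
    apply(expand.grid(x = x0 + 0:1, y = y0 + 0:1, z = z0), 1, paste,
          collapse = ","))
  if (!block_ok) stop("tumor VOI is not a 2 x 2 x 1 block")

  cand <- as.matrix(expand.grid(x = (x0 - 2):(x0 + 3),
                                y = (y0 - 2):(y0 + 3),
                                z = (z0 - 2):(z0 + 2)))
  axdist <- function(v, lo, hi) pmax(0, pmax(lo - v, v - hi))
  dx <- axdist(cand[, 1], x0, x0 + 1L)
  dy <- axdist(cand[, 2], y0, y0 + 1L)
  dz <- axdist(cand[, 3], z0, z0)
  cheb <- pmax(dx, pmax(dy, dz))
  in_plane <- (cand[, 3] == z0) | (cand[, 1] %in% c(x0, x0 + 1L)) |
              (cand[, 2] %in% c(y0, y0 + 1L))
  cand <- cand[cheb == 2 & in_plane, , drop = FALSE]

  center <- c(x0 + 0.5, y0 + 0.5, z0)
  eu <- sqrt((cand[, 1] - center[1])^2 + (cand[, 2] - center[2])^2 +
             (cand[, 3] - center[3])^2)
  ord <- order(eu, cand[, 3], cand[, 2], cand[, 1])
  voi <- cand[ord[1:34], , drop = FALSE]
  if (any(voi < 0) || any(sweep(voi, 2, grid$dims, ">=")))
    stop("tumor is too close to the grid edge for the 34-voxel normal VOI")
  storage.mode(voi) <- "integer"
  dimnames(voi) <- list(NULL, c("x", "y", "z"))
  voi
}

#' Tumor-to-normal concentration ratio
#'
#' Mean voxel value in the tumor VOI divided by the mean voxel value in
#' the normal-tissue VOI.
#'
#' @param volume 3-D array (a reconstructed volume).
#' @param tumor_voi,normal_voi 0-based voxel index matrices; must be
#'   disjoint and inside the grid.
#' @param grid the [voxel_grid()].
#' @return dimensionless ratio.
#' @export
tnc_ratio <- function(volume, tumor_voi, normal_voi, grid) {
  lt <- flat_index(grid, tumor_voi)
  ln <- flat_index(grid, normal_voi)
  if (length(intersect(lt, ln)) > 0) stop("tumor and normal VOI overlap")
  mn <- mean(volume[ln])
  if (mn == 0) stop("undefined TNC ratio: normal VOI mean is zero")
  mean(volume[lt]) / mn
}

#' Signal-to-noise ratio with randomly placed liver VOIs
#'
#' Signal is the mean voxel value in the tumor VOI; noise is the standard
#' deviation of the mean voxel values of `n_samples` randomly placed
#' tumor-sized (2 x 2 x 1) VOIs in the liver, none intersecting the tumor
#' VOI. Placement is uniform over eligible block origins, without
#' replacement, and seeded. The ratio is invariant under rescaling of the
#' volume.
#'
#' @param volume 3-D array.
#' @param tumor_voi 0-based tumor voxel indices (4 x 3).
#' @param liver_mask logical 3-D array.
#' @param grid the [voxel_grid()].
#' @param n_samples number of sample VOIs, default 20.
#' @param seed integer seed for placement.
#' @return SNR (possibly `Inf` with a warning when the noise is zero).
#' @export
snr <- function(volume, tumor_voi, liver_mask, grid, n_samples = 20, seed = 1) {
  d <- grid$dims
  block <- liver_mask &
    shift_mask(liver_mask, c(1, 0, 0)) &
    shift_mask(liver_mask, c(0, 1, 0)) &
    shift_mask(liver_mask, c(1, 1, 0))
  origins <- which(block)
  tumor_lin <- flat_index(grid, tumor_voi)
  # a block at origin o intersects the tumor iff o is a tumor voxel shifted
  # back by one of the four in-plane block offsets
  excl <- unlist(lapply(list(c(0L, 0L, 0L), c(-1L, 0L, 0L),
                             c(0L, -1L, 0L), c(-1L, -1L, 0L)), function(o) {
    og <- sweep(tumor_voi, 2, -o, "-")
    keep <- og[, 1] >= 0 & og[, 2] >= 0
    if (!any(keep)) return(integer(0))
    flat_index(grid, og[keep, , drop = FALSE])
  }))
  origins <- setdiff(origins, excl)
  if (length(origins) < n_samples)
    stop("fewer than ", n_samples, " placeable sample VOIs in the liver")
  picks <- with_seed(seed, sample(origins, n_samples))
  means <- vapply(picks, function(o) {
    mean(volume[flat_index(grid, block_voxels(unflat_index(grid, o)))])
  }, numeric(1))
  s <- stats::sd(means)
  if (s == 0) {
    warning("zero noise estimate: returning infinite SNR")
    return(Inf)
  }
  mean(volume[tumor_lin]) / s
}

block_voxels <- function(origin) {
  origin <- rbind_idx(origin)
  cbind(origin[1, 1] + c(0L, 1L, 0L, 1L),
        origin[1, 2] + c(0L, 0L, 1L, 1L),
        origin[1, 3] + c(0L, 0L, 0L, 0L))
}

#' Classify one observer call against the case truth
#'
#' Positive case: a call with coordinates within `tolerance_mm` of the true
#' centre is a true positive (`"TP"`); a call outside tolerance is a
#' misplaced lesion (`"misplaced"`, which is a positive call for ROC
#' purposes and a lesion-level false positive); no call is `"FN"`.
#' Negative case: a call is `"FP_case"`, no call is `"TN"`.
#'
#' @param called logical; did the observer call a lesion.
#' @param coords_mm world mm coordinates of the call (or `NULL`).
#' @param truth_positive logical; does the case contain a lesion.
#' @param truth_center_mm true lesion centre (or `NULL`).
#' @param tolerance_mm coordinate-match tolerance, default 8.84 mm
#'   (2 voxels).
#' @return one of `"TP"`, `"misplaced"`, `"FN"`, `"FP_case"`, `"TN"`.
#' @export
classify_case <- function(called, coords_mm = NULL, truth_positive,
                          truth_center_mm = NULL, tolerance_mm = 8.84) {
  if (called && is.null(coords_mm))
    stop("a positive call must carry coordinates")
  if (!truth_positive) return(if (called) "FP_case" else "TN")
  if (!called) return("FN")
  if (is.null(truth_center_mm)) stop("positive truth must carry a centre")
  d <- sqrt(sum((coords_mm - truth_center_mm)^2))
  if (d <= tolerance_mm) "TP" else "misplaced"
}

#' Summarize observer assessments into a confusion table
#'
#' Aggregates per-case assessments against the truth under scenario
#' `"AL"` (all lesions) or `"DL"` (detectable lesions). Under DL, positive
#' cases flagged as not detectable are reclassified as negatives before
#' counting, so a call on such a case — including a misplaced call —
#' becomes a case-level false positive. Detection rate is
#' `100 * TP / n_positive` and accuracy `100 * (TP + TN) / n_cases`,
#' computed exactly and reported unrounded (the tables' convention is one
#' decimal).
#'
#' @param assessments data frame with columns `case_id`, `arm`, `called`
#'   (logical), `confidence` (1-3), `x_mm`, `y_mm`, `z_mm` (NA when not
#'   called).
#' @param truths data frame with columns `case_id`, `positive` (logical),
#'   `x_mm`, `y_mm`, `z_mm` (NA for negatives), `detectable` (logical,
#'   used by DL).
#' @param scenario `"AL"` or `"DL"`.
#' @param tolerance_mm coordinate-match tolerance, default 8.84.
#' @return a data frame of class `confusion_summary`, one row per arm,
#'   with counts (`tp`, `misplaced`, `fn`, `fp_case`, `fp_lesion`, `tn`)
#'   and rates (`detection_rate`, `accuracy`, in percent).
#' @export
summarize_assessments <- function(assessments, truths,
                                  scenario = c("AL", "DL"),
                                  tolerance_mm = 8.84) {
  scenario <- match.arg(scenario)
  need <- setdiff(truths$case_id, assessments$case_id)
  if (length(need) > 0)
    stop("missing assessments for cases: ", paste(need, collapse = ", "))
  tr <- truths
  if (scenario == "DL") tr$positive <- tr$positive & tr$detectable

  arms <- unique(assessments$arm)
  rows <- lapply(arms, function(a) {
    as_a <- assessments[assessments$arm == a, ]
    miss <- setdiff(tr$case_id, as_a$case_id)
    if (length(miss) > 0)
      stop("missing assessments for arm ", a, ", cases: ",
           paste(miss, collapse = ", "))
    m <- match(as_a$case_id, tr$case_id)
    outc <- vapply(seq_len(nrow(as_a)), function(i) {
      ti <- m[i]
      classify_case(
        called = as_a$called[i],
        coords_mm = if (as_a$called[i]) c(as_a$x_mm[i], as_a$y_mm[i], as_a$z_mm[i]),
        truth_positive = tr$positive[ti],
        truth_center_mm = if (tr$positive[ti]) c(tr$x_mm[ti], tr$y_mm[ti], tr$z_mm[ti]),
        tolerance_mm = tolerance_mm)
    }, character(1))
    n_cases <- nrow(as_a)
    n_pos <- sum(tr$positive[m])
    tp <- sum(outc == "TP"); mis <- sum(outc == "misplaced")
    fn <- sum(outc == "FN"); fpc <- sum(outc == "FP_case")
    tn <- sum(outc == "TN")
    data.frame(arm = a, scenario = scenario, n_cases = n_cases,
               n_positive = n_pos, n_negative = n_cases - n_pos,
               tp = tp, misplaced = mis, fn = fn, fp_case = fpc,
               fp_lesion = fpc + mis, tn = tn,
               detection_rate = 100 * tp / n_pos,
               accuracy = 100 * (tp + tn) / n_cases)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("confusion_summary", class(out))
  out
}

#' @export
print.confusion_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$detection_rate <- round(y$detection_rate, 1)
  y$accuracy <- round(y$accuracy, 1)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Suspicion rating from an observer assessment
#'
#' Monotone 1-6 rating combining the binary call and the 1-3 confidence:
#' no/certain is 1 (definitely no lesion) up to yes/certain at 6.
#'
#' @param called logical (vectorized).
#' @param confidence integer 1 (low/uncertain) to 3 (high/certain).
#' @return integer rating 1..6.
#' @export
rating <- function(called, confidence) {
  if (any(!confidence %in% 1:3)) stop("confidence must be 1, 2 or 3")
  ifelse(called, 3L + as.integer(confidence), 4L - as.integer(confidence))
}

#' Empirical ROC area with bootstrap confidence interval
#'
#' The empirical AUC `P(rating_pos > rating_neg) + 0.5 P(tie)`, computed
#' via the Mann-Whitney rank statistic, with a seeded percentile bootstrap
#' interval (cases resampled within class).
#'
#' @param ratings numeric suspicion ratings.
#' @param labels logical (or 0/1) true class per rating.
#' @param n_boot bootstrap replicates, default 2000.
#' @param seed integer seed.
#' @param conf confidence level, default 0.95.
#' @return list with `auc`, `ci` (length 2), `n_pos`, `n_neg`.
#' @export
empirical_auc <- function(ratings, labels, n_boot = 2000, seed = 1,
                          conf = 0.95) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute an AUC")
  auc_stat <- function(r, l) {
    rk <- rank(r)
    (sum(rk[l]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  auc <- auc_stat(ratings, labels)
  pos <- ratings[labels]; neg <- ratings[!labels]
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    rp <- sample(pos, n_pos, replace = TRUE)
    rn <- sample(neg, n_neg, replace = TRUE)
    auc_stat(c(rp, rn), c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  list(auc = auc,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n_pos = n_pos, n_neg = n_neg)
}
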