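std_tumor <- function(origin = c(10L, 12L, 8L)) {
  cbind(x = origin[1] + c(0L, 1L, 0L, 1L),
        y = origin[2] + c(0L, 0L, 1L, 1L),
        z = origin[3])
}

test_that("the normal-tissue VOI has 34 voxels, none adjacent to the tumor", {
  g <- voxel_grid(c(32, 32, 16), 4.42)
  tum <- std_tumor()
  voi <- build_normal_voi(tum, g)
  expect_equal(nrow(voi), 34L)
  # Chebyshev distance >= 2 from every tumor voxel
  for (i in seq_len(nrow(voi)))
    for (j in seq_len(nrow(tum)))
      expect_gte(max(abs(voi[i, ] - tum[j, ])), 2)
  # in one of the three orthogonal voxel planes of the block
  expect_true(all(voi[, "z"] == 8L | voi[, "x"] %in% c(10L, 11L) |
                  voi[, "y"] %in% c(12L, 13L)))
  # disjoint from the tumor
  expect_equal(nrow(merge(as.data.frame(voi), as.data.frame(tum))), 0L)
})

test_that("normal VOI construction is translation-equivariant", {
  g <- voxel_grid(c(32, 32, 16), 4.42)
  a <- build_normal_voi(std_tumor(c(10L, 12L, 8L)), g)
  b <- build_normal_voi(std_tumor(c(11L, 13L, 9L)), g)
  expect_equal(b, a + matrix(rep(c(1L, 1L, 1L), each = 34), 34, 3),
               ignore_attr = TRUE)
  expect_error(build_normal_voi(std_tumor(c(0L, 12L, 8L)), g), "edge")
  expect_error(build_normal_voi(std_tumor()[1:3, ], g), "4-voxel")
})

test_that("TNC ratio is the ratio of VOI means", {
  g <- voxel_grid(c(32, 32, 16), 4.42)
  tum <- std_tumor()
  nor <- build_normal_voi(tum, g)
  u <- array(5, dim = g$dims)
  expect_equal(tnc_ratio(u, tum, nor, g), 1)
  v <- array(3, dim = g$dims)
  v[spectlab:::flat_index(g, tum)] <- 24
  expect_equal(tnc_ratio(v, tum, nor, g), 8)
  z <- array(0, dim = g$dims)
  expect_error(tnc_ratio(z, tum, nor, g), "zero")
  expect_error(tnc_ratio(u, tum, tum, g), "overlap")
})

test_that("SNR estimates the noise of tumor-sized VOI means", {
  cfg <- small_phantom_config(liver_cv = 0)
  case <- generate_phantom(cfg, 2)
  g <- case$grid
  tum <- std_tumor(c(20L, 18L, 16L))
  s_vox <- 4
  set.seed(15)
  vol <- array(100 + rnorm(prod(g$dims), sd = s_vox), dim = g$dims)
  got <- snr(vol, tum, case$masks$liver, g, n_samples = 20, seed = 3)
  # sd of a 4-voxel mean is s/2; 20 samples estimate it within ~40%
  expect_gt(got, 100 / (s_vox / 2) / 1.4)
  expect_lt(got, 100 / (s_vox / 2) * 1.4)
  expect_identical(got, snr(vol, tum, case$masks$liver, g, 20, seed = 3))
  expect_equal(got, snr(3 * vol, tum, case$masks$liver, g, 20, seed = 3))
  tiny_mask <- array(FALSE, g$dims); tiny_mask[10:12, 10:12, 8] <- TRUE
  expect_error(snr(vol, tum, tiny_mask, g, 20, 1), "placeable")
  flat <- array(1, dim = g$dims)
  expect_warning(inf_snr <- snr(flat, tum, case$masks$liver, g, 20, 1),
                 "infinite")
  expect_identical(inf_snr, Inf)
})

test_that("case classification distinguishes TP, misplaced, FN, FP and TN", {
  ctr <- c(10, -20, 30)
  expect_identical(classify_case(FALSE, NULL, FALSE), "TN")
  expect_identical(classify_case(TRUE, c(100, 100, 100), FALSE), "FP_case")
  expect_identical(classify_case(FALSE, NULL, TRUE, ctr), "FN")
  expect_identical(classify_case(TRUE, ctr, TRUE, ctr), "TP")
  # 3 voxels (13.26 mm) off with a 2-voxel (8.84 mm) tolerance
  expect_identical(classify_case(TRUE, ctr + c(13.26, 0, 0), TRUE, ctr,
                                 tolerance_mm = 8.84), "misplaced")
  expect_identical(classify_case(TRUE, ctr + c(8.8, 0, 0), TRUE, ctr,
                                 tolerance_mm = 8.84), "TP")
  expect_error(classify_case(TRUE, NULL, TRUE, ctr), "coordinates")
})

test_that("summaries reproduce exact rational accounting", {
  truths <- study_truths()
  asmt <- study_assessments()
  al <- summarize_assessments(asmt, truths, "AL")
  al <- al[match(c("fAC_OSEM", "fMC_OSEM", "MC_OSEM"), al$arm), ]
  expect_equal(al$detection_rate, 100 * c(8, 11, 13) / 26)
  expect_equal(al$accuracy, 100 * (c(8, 11, 13) + c(9, 6, 7)) / 37)
  expect_equal(al$fp_lesion, c(4, 10, 5))
  # all-correct limit
  perfect <- asmt[asmt$arm == "MC_OSEM", ]
  m <- match(perfect$case_id, truths$case_id)
  perfect$called <- truths$positive[m]
  perfect[, c("x_mm", "y_mm", "z_mm")] <- truths[m, c("x_mm", "y_mm", "z_mm")]
  p <- summarize_assessments(perfect, truths, "AL")
  expect_equal(p$detection_rate, 100)
  expect_equal(p$accuracy, 100)
  expect_error(summarize_assessments(asmt[-1, ], truths, "AL"), "missing")
})

test_that("the DL scenario reclassifies undetectable lesions as negatives", {
  truths <- study_truths()
  asmt <- study_assessments()
  dl <- summarize_assessments(asmt, truths, "DL")
  dl <- dl[match(c("fAC_OSEM", "fMC_OSEM", "MC_OSEM"), dl$arm), ]
  al <- summarize_assessments(asmt, truths, "AL")
  al <- al[match(c("fAC_OSEM", "fMC_OSEM", "MC_OSEM"), al$arm), ]
  expect_equal(dl$n_positive, rep(19L, 3))
  expect_equal(dl$detection_rate, 100 * c(8, 11, 13) / 19)
  # misplaced calls on reclassified cases become case-level false positives
  expect_equal(dl$misplaced, c(0, 4, 1))
  expect_equal(dl$fp_case, c(4, 6, 4))
  # with the TP set retained, shrinking the denominator cannot decrease
  # the detection rate
  expect_true(all(dl$detection_rate >= al$detection_rate))
})

test_that("ratings are a monotone map of call and confidence", {
  expect_identical(rating(FALSE, 3), 1L)
  expect_identical(rating(TRUE, 3), 6L)
  seq6 <- rating(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
                 c(3, 2, 1, 1, 2, 3))
  expect_identical(seq6, 1:6)
  expect_error(rating(TRUE, 4), "confidence")
})

test_that("empirical AUC equals the exhaustive pair-count oracle", {
  expect_equal(empirical_auc(c(1, 2, 5, 6), c(0, 0, 1, 1), n_boot = 10)$auc, 1)
  expect_equal(empirical_auc(rep(3, 8), rep(0:1, 4), n_boot = 10)$auc, 0.5)
  set.seed(16)
  for (rep_i in 1:5) {
    r <- sample(1:6, 12, replace = TRUE)
    l <- c(rep(TRUE, 5), rep(FALSE, 7))
    got <- empirical_auc(r, l, n_boot = 50, seed = rep_i)
    # brute-force double loop over all positive/negative pairs
    pos <- r[l]; neg <- r[!l]; acc <- 0
    for (p in pos) for (q in neg) acc <- acc + (p > q) + 0.5 * (p == q)
    expect_equal(got$auc, acc / (length(pos) * length(neg)))
    expect_true(got$ci[1] <= got$auc && got$auc <= got$ci[2])
    # invariance under strictly monotone transforms
    expect_equal(empirical_auc(exp(2 * r), l, n_boot = 10)$auc, got$auc)
  }
  expect_error(empirical_auc(1:5, rep(TRUE, 5), n_boot = 10), "both classes")
})
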