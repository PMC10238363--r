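# dense-matrix test harness: an explicit nonnegative system matrix with
# forward/adjoint closures, the ground truth for the OSEM engine
dense_system <- function(m = 12, n = 8, seed = 1) {
  set.seed(seed)
  A <- matrix(runif(m * n), m, n)
  A[A < 0.2] <- 0
  A <- A + 0.05  # strictly positive column sums
  list(A = A,
       forward = function(x, idx) as.numeric(A[idx, , drop = FALSE] %*% as.numeric(x)),
       adjoint = function(y, idx) as.numeric(t(A[idx, , drop = FALSE]) %*% as.numeric(y)))
}

# independent brute-force implementation of one full OSEM pass
osem_oracle_pass <- function(A, y, x, subsets, floor_ = 1e-12, cap = 1e4) {
  for (idx in subsets) {
    As <- A[idx, , drop = FALSE]
    fp <- as.numeric(As %*% x)
    ratio <- pmin(y[idx] / pmax(fp, floor_), cap)
    ratio[y[idx] == 0] <- 0
    num <- as.numeric(t(As) %*% ratio)
    den <- pmax(colSums(As), floor_)
    x <- x * num / den
  }
  x
}

test_that("OSEM with a matched pair holds the MLEM fixed point", {
  sys <- dense_system()
  x_true <- rep(2.5, 8)
  y <- sys$forward(x_true, 1:12)
  rec <- osem(y, sys$forward, sys$adjoint,
              osem_config(n_iter = 3, n_subsets = 2, init = 2.5),
              subsets = list(1:6, 7:12))
  expect_lt(max(abs(rec$values - x_true) / x_true), 1e-10)
})

test_that("one OSEM pass matches the brute-force dense-matrix oracle", {
  sys <- dense_system(seed = 5)
  set.seed(6)
  x0 <- runif(8, 0.5, 2)
  y <- rpois(12, sys$forward(runif(8, 1, 4), 1:12))
  subsets <- list(c(1, 3, 5, 7, 9, 11), c(2, 4, 6, 8, 10, 12))
  rec <- osem(as.numeric(y), sys$forward, sys$adjoint,
              osem_config(n_iter = 1, n_subsets = 2, init = x0),
              subsets = subsets)
  want <- osem_oracle_pass(sys$A, y, x0, subsets)
  expect_equal(as.numeric(rec$values), want, tolerance = 1e-12)
})

test_that("MLEM converges on a noise-free invertible toy system", {
  set.seed(8)
  n <- 24
  A <- diag(n) + 0.1 * matrix(runif(n * n), n, n)
  fw <- function(x, idx) as.numeric(A[idx, , drop = FALSE] %*% as.numeric(x))
  ad <- function(y, idx) as.numeric(t(A[idx, , drop = FALSE]) %*% as.numeric(y))
  x_true <- rep(c(1, 3), each = n / 2)  # two-level phantom
  y <- fw(x_true, 1:n)
  rec <- osem(y, fw, ad, osem_config(n_iter = 50, n_subsets = 1),
              subsets = list(1:n))
  expect_lt(max(abs(rec$values - x_true) / x_true), 0.05)
  # total modelled counts approach the data total monotonically
  gaps <- abs(rec$history - sum(y))
  expect_true(all(diff(gaps) <= 1e-8))
})

test_that("one-subset OSEM is exactly MLEM", {
  sys <- dense_system(seed = 12)
  set.seed(13)
  y <- rpois(12, 20)
  r1 <- osem(as.numeric(y), sys$forward, sys$adjoint,
             osem_config(n_iter = 4, n_subsets = 1, init = 1),
             subsets = list(1:12))
  # manual MLEM with the same operators
  x <- rep(1, 8)
  den <- sys$adjoint(rep(1, 12), 1:12)
  for (k in 1:4) {
    fp <- sys$forward(x, 1:12)
    ratio <- y / pmax(fp, 1e-12); ratio[y == 0] <- 0
    x <- x * sys$adjoint(ratio, 1:12) / pmax(den, 1e-12)
  }
  expect_equal(as.numeric(r1$values), x, tolerance = 1e-14)
})

test_that("reconstruction arms carry the prescribed provenance", {
  cfg <- tiny_phantom_config()
  case <- generate_phantom(cfg, 3)
  geom <- tiny_geometry()
  ex <- mc_forward(case$activity, case$mu_171, case$mu_245, geom, case$grid,
                   n_photons = 2e5, seed = 4)
  counts <- sample_counts(ex, 5)

  fac <- reconstruct_arm(counts, case, "fAC_OSEM", geom, seed = 6)
  expect_equal(fac$config$n_iter, 2L)
  expect_equal(fac$config$n_subsets, 10L)
  expect_match(fac$filter, "butterworth")
  expect_true(all(fac$values >= 0))

  mc <- reconstruct_arm(counts, case, "MC_OSEM", geom, seed = 7,
                        config = osem_config(n_iter = 5, n_subsets = 10,
                                             photons_per_forward = 5e3,
                                             floor_frac = 0.02))
  expect_equal(mc$config$n_iter, 5L)
  expect_equal(mc$config$n_subsets, 10L)
  expect_identical(mc$filter, "none")

  # fMC with shared seeds equals the Gaussian-filtered MC volume
  fmc <- reconstruct_arm(counts, case, "fMC_OSEM", geom, seed = 7,
                         config = osem_config(n_iter = 5, n_subsets = 10,
                                              photons_per_forward = 5e3,
                                              floor_frac = 0.02))
  expect_equal(fmc$values,
               gaussian_lp(mc$values, 3, case$grid$voxel_size),
               tolerance = 1e-12)
  expect_error(reconstruct_arm(counts, case, "OSEM3D", geom),
               "valid arms")
})

test_that("degenerate inputs are handled: zero counts and subset mismatch", {
  geom <- tiny_geometry(n_proj = 20L)
  cfg <- tiny_phantom_config()
  case <- generate_phantom(cfg, 2)
  mdl <- analytic_model(case, geom)
  zero <- sinogram(array(0, c(32, 16, 20)), geom, "counts")
  expect_warning(rec <- osem(zero, mdl$forward, mdl$adjoint,
                             osem_config(n_iter = 1, n_subsets = 10)),
                 "all-zero")
  expect_true(all(rec$values == 0))
  expect_error(osem(zero, mdl$forward, mdl$adjoint,
                    osem_config(n_iter = 1, n_subsets = 7)),
               "divisible")
})

test_that("spect_recon methods expose fit diagnostics", {
  sys <- dense_system(seed = 21)
  set.seed(22)
  y <- rpois(12, sys$forward(runif(8, 1, 3), 1:12))
  rec <- osem(as.numeric(y), sys$forward, sys$adjoint,
              osem_config(n_iter = 5, n_subsets = 1, keep_fitted = TRUE),
              subsets = list(1:12))
  expect_length(fitted(rec), 12)
  expect_length(residuals(rec), 12)
  expect_equal(residuals(rec, "raw"), y - fitted(rec))
  sim <- simulate(rec, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_true(all(sim[[1]] >= 0))
  expect_output(print(rec), "spect_recon")
  expect_output(print(summary(rec)), "iterations")
})
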