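test_that("collimator FWHM is the linear distance model", {
  cm <- collimator_model(fwhm_intrinsic = 4, fwhm_slope = 0.05)
  expect_equal(cdr_fwhm(0, cm), 4)
  expect_equal(cdr_fwhm(100, cm), 9)
  d <- sort(runif(20, 0, 400))
  expect_true(all(diff(cdr_fwhm(d, cm)) >= 0))
  expect_error(cdr_fwhm(-1, cm), ">= 0")
})

test_that("unattenuated point source projects equally at every angle", {
  d <- c(32L, 32L, 16L)
  g <- voxel_grid(d, 4.42)
  act <- array(0, dim = d); act[16, 16, 8] <- 1000
  mu <- array(0, dim = d)
  geom <- tiny_geometry(n_proj = 20L)
  s <- analytic_forward(act, mu, geom, g, cdr = "off")
  tot <- apply(s$values, 3, sum)
  expect_lt(diff(range(tot)) / mean(tot), 0.01)
})

test_that("attenuation follows Beer-Lambert against a scalar oracle", {
  d <- c(32L, 32L, 16L)
  g <- voxel_grid(d, 4.42)
  act <- array(0, dim = d); act[16, 4, 8] <- 1
  mu <- array(0, dim = d)
  mu[, 8:20, ] <- 1.5 / (13 * 4.42)   # slab of optical depth 1.5 on the ray
  geom <- tiny_geometry(n_proj = 4L)
  s0 <- analytic_forward(act, array(0, dim = d), geom, g, cdr = "off")
  s1 <- analytic_forward(act, mu, geom, g, cdr = "off")
  # angle 1 points along +y through the slab; oracle = scalar exponential
  # of the discretized line integral from the source voxel to the edge
  path <- sum(mu[16, 5:32, 8]) * 4.42 + 0.5 * mu[16, 4, 8] * 4.42
  expect_equal(sum(s1$values[, , 1]) / sum(s0$values[, , 1]),
               exp(-path), tolerance = 1e-10)
  expect_equal(exp(-path), exp(-1.5), tolerance = 1e-12)
})

test_that("analytic projector is linear and scales exactly with time and activity", {
  d <- c(32L, 32L, 16L)
  g <- voxel_grid(d, 4.42)
  set.seed(4)
  a <- array(runif(prod(d)), dim = d)
  b <- array(runif(prod(d)), dim = d)
  mu <- array(0.01 * runif(prod(d)), dim = d)
  geom <- tiny_geometry(n_proj = 8L)
  pa <- analytic_forward(a, mu, geom, g)$values
  pb <- analytic_forward(b, mu, geom, g)$values
  pab <- analytic_forward(a + b, mu, geom, g)$values
  expect_equal(pab, pa + pb, tolerance = 1e-12)
  expect_equal(analytic_forward(2 * a, mu, geom, g)$values, 2 * pa,
               tolerance = 1e-12)
  geom2 <- tiny_geometry(n_proj = 8L, time_per_proj_s = 60)
  expect_equal(analytic_forward(a, mu, geom2, g)$values, 2 * pa,
               tolerance = 1e-12)
})

test_that("forward and adjoint are an exact transpose pair", {
  d <- c(32L, 32L, 16L)
  g <- voxel_grid(d, 4.42)
  set.seed(11)
  x <- array(runif(prod(d)), dim = d)
  y <- array(runif(32 * 16 * 8), dim = c(32, 16, 8))
  mu <- array(0.008 * runif(prod(d)), dim = d)
  geom <- tiny_geometry(n_proj = 8L)
  for (cdr in c("off", "on")) {
    lhs <- sum(analytic_forward(x, mu, geom, g, cdr)$values * y)
    rhs <- sum(x * analytic_adjoint(y, mu, geom, g, cdr))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("Monte Carlo projector handles empty activity and is reproducible", {
  d <- c(32L, 32L, 16L)
  g <- voxel_grid(d, 4.42)
  geom <- tiny_geometry(n_proj = 8L)
  mu <- array(0.0144, dim = d)
  zero <- array(0, dim = d)
  s0 <- mc_forward(zero, mu, mu, geom, g, n_photons = 1e4, seed = 1)
  expect_true(all(s0$values == 0))
  act <- array(0, dim = d); act[14:18, 14:18, 7:9] <- 100
  s1 <- mc_forward(act, mu, mu, geom, g, n_photons = 1e4, seed = 5)
  s2 <- mc_forward(act, mu, mu, geom, g, n_photons = 1e4, seed = 5)
  expect_identical(s1$values, s2$values)
  expect_error(mc_forward(act, mu, mu, geom, g, n_photons = 0, seed = 1),
               ">= 1")
})

test_that("scatter-free Monte Carlo agrees with the analytic projector", {
  d <- c(32L, 32L, 16L)
  g <- voxel_grid(d, 4.42)
  act <- array(0, dim = d); act[14:18, 14:18, 7:9] <- 1000
  co <- (1:32 - 16.5)
  circ <- outer(co^2, co^2, "+") <= 14^2
  mu <- array(0.0144 * rep(circ, 16), dim = d)
  geom <- tiny_geometry(n_proj = 8L,
                        photopeak_abundances = c("171" = 1, "245" = 0))
  ana <- analytic_forward(act, mu, geom, g, cdr = "off")

  # forced-detection estimator: tight agreement
  mf <- mc_forward(act, mu, mu, geom, g, n_photons = 1e5, seed = 2,
                   scatter = FALSE, mode = "forced", cdr = FALSE,
                   energy_res_fwhm = 0)
  expect_lt(abs(sum(mf$values) / sum(ana$values) - 1), 0.05)

  # naive analog tracker with binary acceptance cone at 1e6 photons
  ma <- mc_forward(act, mu, mu, geom, g, n_photons = 1e6, seed = 3,
                   scatter = FALSE, mode = "analog", cdr = FALSE,
                   energy_res_fwhm = 0)
  expect_gt(sum(ma$values) / sum(ana$values), 0.95)
  expect_lt(sum(ma$values) / sum(ana$values), 1.05)
})

test_that("mean analog Monte Carlo sinogram is unbiased binwise over seeds", {
  d <- c(32L, 32L, 16L)
  g <- voxel_grid(d, 4.42)
  act <- array(0, dim = d); act[13:19, 13:19, 6:10] <- 1000
  co <- (1:32 - 16.5)
  circ <- outer(co^2, co^2, "+") <= 14^2
  mu <- array(0.0144 * rep(circ, 16), dim = d)
  geom <- tiny_geometry(n_proj = 8L,
                        photopeak_abundances = c("171" = 1, "245" = 0))
  ana <- analytic_forward(act, mu, geom, g, cdr = "off")$values
  n_seeds <- 20
  sims <- vapply(seq_len(n_seeds), function(s)
    mc_forward(act, mu, mu, geom, g, n_photons = 2e5, seed = 100 + s,
               scatter = FALSE, mode = "analog", cdr = FALSE,
               energy_res_fwhm = 0, accept_half_angle_deg = 3)$values,
    array(0, dim = dim(ana)))
  mn <- apply(sims, 1:3, mean)
  se <- apply(sims, 1:3, stats::sd) / sqrt(n_seeds)
  # compare where the expected signal is nontrivial; floor the SE to avoid
  # zero-variance bins
  sel <- ana > 0.1 * max(ana)
  zs <- (mn[sel] - ana[sel]) / pmax(se[sel], 1e-12)
  expect_gt(mean(abs(zs) <= 3), 0.97)
  expect_lt(abs(sum(mn) / sum(ana) - 1), 0.05)
})

test_that("energy-window logic respects Compton kinematics", {
  d <- c(32L, 32L, 16L)
  g <- voxel_grid(d, 4.42)
  act <- array(0, dim = d); act[14:18, 14:18, 7:9] <- 1000
  mu <- array(0.0144, dim = d)
  # photons start at 171 keV and can only lose energy: a window strictly
  # above the photopeak collects nothing even with scatter on
  geom_hi <- tiny_geometry(n_proj = 8L,
                           photopeak_abundances = c("171" = 1, "245" = 0),
                           energy_windows = list(c(245, 0.04)))
  s_hi <- mc_forward(act, mu, mu, geom_hi, g, n_photons = 5e4, seed = 9,
                     scatter = TRUE, energy_res_fwhm = 0)
  expect_true(all(s_hi$values == 0))
  # widening the window to accept scattered energies strictly increases
  # the tally relative to the photopeak-only window
  geom_pk <- tiny_geometry(n_proj = 8L,
                           photopeak_abundances = c("171" = 1, "245" = 0),
                           energy_windows = list(c(171, 0.02)))
  geom_all <- tiny_geometry(n_proj = 8L,
                            photopeak_abundances = c("171" = 1, "245" = 0),
                            energy_windows = list(c(171, 1.4)))
  s_pk <- mc_forward(act, mu, mu, geom_pk, g, n_photons = 5e4, seed = 9,
                     scatter = TRUE, energy_res_fwhm = 0)
  s_all <- mc_forward(act, mu, mu, geom_all, g, n_photons = 5e4, seed = 9,
                      scatter = TRUE, energy_res_fwhm = 0)
  expect_gt(sum(s_all$values), sum(s_pk$values))
})

test_that("Poisson count sampling has the right moments and is seeded", {
  geom <- tiny_geometry(n_proj = 20L)
  v <- array(100, dim = c(32, 16, 20))
  ex <- sinogram(v, geom, kind = "expectation")
  c1 <- sample_counts(ex, seed = 21)
  c2 <- sample_counts(ex, seed = 21)
  expect_identical(c1$values, c2$values)
  expect_true(all(c1$values == round(c1$values)))
  m <- mean(c1$values)
  expect_gt(m, 99); expect_lt(m, 101)
  vm <- stats::var(as.numeric(c1$values)) / m
  expect_gt(vm, 0.9); expect_lt(vm, 1.1)
  z <- sample_counts(sinogram(v * 0, geom, "expectation"), 1)
  expect_true(all(z$values == 0))
  expect_error(sample_counts(c1, 1), "expectation")
})

test_that("sinogram addition requires identical geometries", {
  geom <- tiny_geometry(n_proj = 8L)
  a <- sinogram(array(1, c(32, 16, 8)), geom, "counts")
  b <- sinogram(array(2, c(32, 16, 8)), geom, "counts")
  expect_equal((a + b)$values, array(3, c(32, 16, 8)))
  expect_equal((a + b)$kind, "counts")
  geom2 <- tiny_geometry(n_proj = 4L)
  d <- sinogram(array(1, c(32, 16, 4)), geom2, "counts")
  expect_error(a + d, "geometries")
})
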