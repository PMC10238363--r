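test_that("radius-1 sphere at an edge-midpoint site is exactly a 2x2x1 block", {
  g <- voxel_grid(c(32, 32, 16), 4.42)
  center <- voxel_center(g, c(10, 10, 8))[1, ] +
    c(0.5, 0.5, 0) * g$voxel_size      # edge-midpoint in x and y
  vox <- voxelize_sphere(center, 1, g)
  expect_equal(nrow(vox), 4L)
  expect_setequal(vox[, "x"], c(10L, 11L))
  expect_setequal(vox[, "y"], c(10L, 11L))
  expect_true(all(vox[, "z"] == 8L))
  # printed lesion volume: 4 voxels of 4.42 mm
  expect_equal(round(nrow(vox) * voxel_volume_ml(g), 2), 0.35)
})

test_that("degenerate and out-of-grid spheres are rejected", {
  g <- voxel_grid(c(32, 32, 16), 4.42)
  center <- voxel_center(g, c(10, 10, 8))[1, ] + c(0.5, 0.5, 0) * g$voxel_size
  expect_error(voxelize_sphere(center, 0.4, g), "no voxel centres")
  edge_center <- voxel_center(g, c(0, 0, 0))[1, ]
  expect_error(voxelize_sphere(edge_center, 2, g), "outside the grid")
  expect_error(lesion_spec(radius_voxels = 1, control_radius_voxels = 1),
               "exceed")
  expect_error(lesion_spec(tnc_target = 1), "> 1")
})

test_that("voxel-centre spheres match a brute-force enumeration oracle", {
  g <- voxel_grid(c(32, 32, 16), 4.42)
  center <- voxel_center(g, c(12, 14, 7))[1, ]
  for (r in c(1, 1.5, 2.2)) {
    vox <- voxelize_sphere(center, r, g)
    # oracle: loop over every voxel centre and test the distance
    want <- 0L
    for (x in 0:31) for (y in 0:31) for (z in 0:15) {
      cc <- voxel_center(g, c(x, y, z))[1, ]
      if (sqrt(sum((cc - center)^2)) <= r * g$voxel_size + 1e-12)
        want <- want + 1L
    }
    expect_equal(nrow(vox), want)
  }
})

test_that("lesion position sampling is uniform over eligible sites", {
  # liver of exactly two eligible sites: two disjoint control spheres
  g <- voxel_grid(c(32, 32, 16), 4.42)
  spec <- lesion_spec()
  mask <- array(FALSE, dim = g$dims)
  put_ball <- function(mask, origin) {
    for (x in 0:31) for (y in 0:31) for (z in 0:15) {
      d <- sqrt((x - origin[1] - 0.5)^2 + (y - origin[2] - 0.5)^2 +
                (z - origin[3])^2)
      if (d <= 3) mask[x + 1, y + 1, z + 1] <- TRUE
    }
    mask
  }
  mask <- put_ball(mask, c(8, 8, 5))
  mask1 <- mask
  mask <- put_ball(mask, c(22, 22, 10))
  expect_equal(length(spectlab:::eligible_sites(mask, g, spec)), 2L)

  draws <- sample_position(mask, g, spec, seed = 31, n = 1e4)
  f1 <- mean(draws[, 1] < 0)
  expect_gt(f1, 0.47); expect_lt(f1, 0.53)

  # single eligible site: returned for any seed; same seed reproducible
  one <- sample_position(mask1, g, spec, seed = 1)
  expect_equal(one, sample_position(mask1, g, spec, seed = 999))
  expect_equal(sample_position(mask, g, spec, seed = 7),
               sample_position(mask, g, spec, seed = 7))
  expect_error(sample_position(array(FALSE, g$dims), g, spec, 1), "empty")
  tiny <- array(FALSE, g$dims); tiny[10, 10, 8] <- TRUE
  expect_error(sample_position(tiny, g, spec, 1), "no eligible")
})

test_that("control VOI mean matches hand enumeration and is linear", {
  g <- voxel_grid(c(32, 32, 16), 4.42)
  center <- voxel_center(g, c(15, 15, 8))[1, ] + c(0.5, 0.5, 0) * g$voxel_size
  act <- array(7, dim = g$dims)
  expect_equal(control_voi_mean(act, g, center, 3), 7)

  set.seed(3)
  act2 <- array(runif(prod(g$dims), 1, 10), dim = g$dims)
  tumor <- voxelize_sphere(center, 1, g)
  # oracle: enumerate the control voxels by hand
  vals <- c(); excl <- apply(tumor, 1, paste, collapse = ",")
  for (x in 0:31) for (y in 0:31) for (z in 0:15) {
    cc <- voxel_center(g, c(x, y, z))[1, ]
    if (sqrt(sum((cc - center)^2)) <= 3 * g$voxel_size + 1e-12 &&
        !(paste(x, y, z, sep = ",") %in% excl))
      vals <- c(vals, act2[x + 1, y + 1, z + 1])
  }
  got <- control_voi_mean(act2, g, center, 3, exclude = tumor)
  expect_equal(got, mean(vals))
  expect_equal(control_voi_mean(2 * act2, g, center, 3, exclude = tumor),
               2 * got)
})

test_that("the lesion source carries exactly the target concentration ratio", {
  cfg <- tiny_phantom_config(liver_cv = 0.3)
  case <- generate_phantom(cfg, 17)
  spec <- lesion_spec()
  center <- sample_position(case$masks$liver, case$grid, spec, 23)
  src <- make_lesion_source(case, center, spec)
  expect_equal(nrow(src$truth$voxels), 4L)
  expect_identical(src$truth$inserted_concentration,
                   8 * src$truth$local_concentration)
  lin <- spectlab:::flat_index(case$grid, src$truth$voxels)
  expect_true(all(src$activity[lin] == src$truth$inserted_concentration))
  expect_true(all(src$activity[-lin] == 0))

  # uniform liver: local concentration is the liver concentration exactly
  cfg0 <- tiny_phantom_config(liver_cv = 0)
  case0 <- generate_phantom(cfg0, 17)
  src0 <- make_lesion_source(case0, sample_position(case0$masks$liver,
                                                    case0$grid, spec, 29),
                             spec)
  expect_equal(src0$truth$local_concentration, cfg0$conc_liver)

  # cold region: lesion undefined
  cold <- case
  cold$activity <- array(0, dim = case$grid$dims)
  expect_error(make_lesion_source(cold, center, spec), "not positive")
})

test_that("sinogram-domain insertion is additive and scales with TNC", {
  cfg <- tiny_phantom_config()
  case <- generate_phantom(cfg, 5)
  geom <- tiny_geometry()
  ex <- mc_forward(case$activity, case$mu_171, case$mu_245, geom, case$grid,
                   n_photons = 1e5, seed = 6)
  patient <- sample_counts(ex, 7)
  spec <- lesion_spec()
  center <- sample_position(case$masks$liver, case$grid, spec, 8)
  src <- make_lesion_source(case, center, spec)

  zero_map <- array(0, dim = case$grid$dims)
  expect_identical(insert_lesion(patient, case, zero_map, geom, 1e4, 9),
                   patient)

  out <- insert_lesion(patient, case, src$activity, geom, 1e5, 9)
  lesion_total <- sum(out$values) - sum(patient$values)
  expect_gte(lesion_total, 0)
  expect_true(all(out$values >= patient$values))

  # halving the inserted concentration halves the expected lesion counts
  src4 <- src$activity / 2
  t8 <- sum(mc_forward(src$activity, case$mu_171, case$mu_245, geom,
                       case$grid, 1e5, seed = 10)$values)
  t4 <- sum(mc_forward(src4, case$mu_171, case$mu_245, geom,
                       case$grid, 1e5, seed = 11)$values)
  expect_gt(t8 / t4, 1.9); expect_lt(t8 / t4, 2.1)
})
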