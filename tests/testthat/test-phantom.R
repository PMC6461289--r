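test_that("ellipsoid volume matches the closed form", {
  expect_equal(round(ellipsoid_volume(ellipsoid()), 1), 164.9)
  expect_equal(ellipsoid_volume(ellipsoid(c(1, 1, 1))), 4 * pi / 3,
               tolerance = 1e-12)
  expect_equal(ellipsoid_volume(ellipsoid(c(1, 2, 3))), 8 * pi,
               tolerance = 1e-12)
})

test_that("ellipsoid construction enforces its invariants", {
  expect_error(ellipsoid(c(1, -1, 1)), "positive")
  expect_error(ellipsoid(c(0, 1, 1)), "positive")
  expect_error(ellipsoid(intensity = 0), "positive")
})

test_that("base orientations place the long axis as named", {
  long <- c(0, 0, 1)
  par <- euler_matrix(base_orientation("parallel")$rotation) %*% long
  expect_equal(as.numeric(par), long, tolerance = 1e-12)
  ort <- euler_matrix(base_orientation("orthogonal")$rotation) %*% long
  expect_lt(abs(ort[3]), 1e-12) # long axis in the imaging plane
  dia <- euler_matrix(base_orientation("diagonal")$rotation) %*% long
  expect_equal(acos(dia[3]) * 180 / pi, 45, tolerance = 1e-9)
  expect_error(base_orientation("oblique"))
})

test_that("rigid-body sampling respects bounds and seeds", {
  draws <- lapply(1:200, function(s) sample_rigid_transform(seed = s))
  tr <- do.call(rbind, lapply(draws, `[[`, "translation"))
  ro <- do.call(rbind, lapply(draws, `[[`, "rotation"))
  expect_true(all(tr >= -4 & tr <= 4))
  expect_true(all(ro >= -8 & ro <= 8))
  expect_identical(sample_rigid_transform(seed = 11),
                   sample_rigid_transform(seed = 11))
  fixed <- sample_rigid_transform(
    seed = 1, bounds = rigid_bounds(c(0, 0), c(0, 0)))
  expect_equal(fixed$translation, c(0, 0, 0))
  expect_equal(fixed$rotation, c(0, 0, 0))
  expect_error(rigid_bounds(c(2, -2)), "min > max")
})

test_that("the study's grid combinations tile the FoV without interpolation", {
  for (ip in c(0.1, 0.2, 0.5, 1.0, 2.0)) {
    for (tf in c(1.0, 1.2, 1.5, 1.8, 2.0, 3.0)) {
      g <- grid_spec(ip, tf)
      expect_equal(g$matrix_dims * g$voxel_dims, g$fov, tolerance = 1e-9)
    }
  }
  expect_equal(grid_spec(2.0, 1.2)$matrix_dims[3], 15L)
  expect_equal(grid_spec(2.0, 2.0)$matrix_dims[3], 9L)
  expect_error(grid_spec(0.7), "integer multiple")
  expect_error(grid_spec(-1), "positive")
  expect_true(is_isotropic(grid_spec(0.5)))
  expect_false(is_isotropic(grid_spec(0.5, 1.2)))
  expect_equal(voxel_volume(grid_spec(2.0, 3.0)), 24)
})

test_that("k-space DC equals total integrated signal for any pose", {
  e <- ellipsoid()
  g <- grid_spec(2.0, 1.5)
  for (s in 1:5) {
    pose <- list(base_orientation("diagonal"), sample_rigid_transform(seed = s))
    ks <- analytic_kspace(e, g, pose)
    dc <- ks$data[ks$dc_index[1], ks$dc_index[2], ks$dc_index[3]]
    expect_equal(Re(dc), ellipsoid_volume(e), tolerance = 1e-9)
    expect_lt(abs(Im(dc)), 1e-9)
    expect_equal(length(ks$data), prod(g$matrix_dims))
  }
  two <- list(ellipsoid(center = c(5, 0, 0), intensity = 2),
              ellipsoid(c(1, 1, 2), center = c(-6, 0, 0)))
  ks2 <- analytic_kspace(two, g)
  dc2 <- Re(ks2$data[ks2$dc_index[1], ks2$dc_index[2], ks2$dc_index[3]])
  expect_equal(dc2, 2 * ellipsoid_volume(two[[1]]) + ellipsoid_volume(two[[2]]),
               tolerance = 1e-9)
})

test_that("translation changes only the phase of the k-space signal", {
  e <- ellipsoid()
  g <- grid_spec(1.0)
  a <- analytic_kspace(e, g, rigid_transform())
  b <- analytic_kspace(e, g, rigid_transform(translation = c(1.3, -2.1, 0.7)))
  expect_equal(Mod(b$data), Mod(a$data), tolerance = 1e-9)
})

test_that("discrete Parseval identity links k-space and image energy", {
  e <- ellipsoid()
  g <- grid_spec(0.5)
  pose <- list(base_orientation("diagonal"), sample_rigid_transform(seed = 3))
  ks <- analytic_kspace(e, g, pose)
  img <- reconstruct(ks, rescale = FALSE)
  energy_k <- sum(Mod(ks$data)^2) / prod(g$fov)
  energy_img <- sum(img$data^2) * voxel_volume(g)
  expect_equal(energy_img, energy_k, tolerance = 0.01)
  # and both approximate the continuous energy of the indicator
  expect_equal(energy_k / ellipsoid_volume(e), 1, tolerance = 0.06)
})

test_that("simulate_volume equals the explicit k-space + reconstruct route", {
  e <- ellipsoid()
  pose <- list(base_orientation("orthogonal"), sample_rigid_transform(seed = 9))
  for (spec in list(c(1.0, 1.2), c(2.0, 2.0))) {
    g <- grid_spec(spec[1], spec[2])
    a <- reconstruct(analytic_kspace(e, g, pose), rescale = FALSE)
    b <- simulate_volume(e, g, pose, rescale = FALSE)
    expect_identical(a$data, b$data)
  }
})

test_that("reconstruction is equivariant under whole-voxel translations", {
  e <- ellipsoid()
  g <- grid_spec(1.0)
  base <- simulate_volume(e, g, rescale = FALSE)
  shifted <- simulate_volume(
    e, g, rigid_transform(translation = c(1, 0, 0)), rescale = FALSE)
  n <- g$matrix_dims[1]
  rolled <- base$data[c(n, seq_len(n - 1)), , ]
  expect_equal(shifted$data, rolled, tolerance = 1e-9)
})

test_that("rescaled reconstructions span [0, 1]", {
  img <- simulate_volume(ellipsoid(), grid_spec(0.5, 1.8))
  expect_equal(min(img$data), 0)
  expect_equal(max(img$data), 1)
  expect_equal(dim(img$data), grid_spec(0.5, 1.8)$matrix_dims)
})

test_that("rasterization oracle gives exact fractions in the limit cases", {
  g <- grid_spec(1.0)
  big <- ellipsoid(c(10, 10, 10))
  orc <- rasterize_oracle(big, g, subdivisions = 3)
  ctr <- g$matrix_dims %/% 2 + 1
  expect_equal(orc$data[ctr[1], ctr[2], ctr[3]], 1.0) # deep inside
  expect_equal(orc$data[1, 1, 1], 0.0)                # far outside
  vol <- sum(rasterize_oracle(ellipsoid(), g, subdivisions = 4)$data) *
    voxel_volume(g)
  expect_equal(vol, ellipsoid_volume(ellipsoid()), tolerance = 0.005)
})

test_that("reconstruction agrees with the oracle, degrading with voxel size", {
  e <- ellipsoid()
  pose <- list(base_orientation("diagonal"), sample_rigid_transform(seed = 5))
  mad <- vapply(c(0.5, 1.0, 2.0), function(ip) {
    g <- grid_spec(ip)
    img <- simulate_volume(e, g, pose, rescale = FALSE)
    orc <- rasterize_oracle(e, g, pose, subdivisions = 6)
    mean(abs(img$data - orc$data))
  }, 0)
  expect_true(all(diff(mad) > 0)) # coarser voxels, worse agreement
  expect_lt(mad[1], 0.05)
})
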