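test_that("ground truth generation is deterministic and watertight", {
  spec <- phantom_spec(case_id = "d", n_teeth = 3, arch_radius_mm = 5,
                       tooth_height_mm = 3, rng_seed = 3,
                       surface_resolution_mm = 0.3)
  m1 <- generate_ground_truth(spec)
  m2 <- generate_ground_truth(spec)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  expect_true(is_watertight(m1))
  expect_gt(mesh_area_volume(m1)[["volume"]], 0)
})

test_that("single-tooth phantom is a closed genus-0 surface", {
  spec <- phantom_spec(case_id = "one", n_teeth = 1, arch_radius_mm = 4,
                       tooth_height_mm = 2.5, rng_seed = 5,
                       surface_resolution_mm = 0.3)
  m <- generate_ground_truth(spec)
  top <- mesh_topology(m)
  expect_true(top$closed)
  expect_identical(top$euler, 2L)
})

test_that("six-tooth phantom example is watertight with positive volume", {
  spec <- phantom_spec(case_id = "six", n_teeth = 6, rng_seed = 42,
                       arch_radius_mm = 6.5, surface_resolution_mm = 0.3)
  m <- generate_ground_truth(spec)
  expect_true(is_watertight(m))
  expect_gt(mesh_area_volume(m)[["volume"]], 0)
})

test_that("degenerate phantom parameters are rejected", {
  expect_error(phantom_spec(arch_radius_mm = 0), class = "mf_invalid_spec")
  expect_error(phantom_spec(n_teeth = 0), class = "mf_invalid_spec")
  expect_error(phantom_spec(tooth_height_mm = -1), class = "mf_invalid_spec")
  expect_error(device_model("x", hu_air = 100, hu_stone = 0),
               class = "mf_invalid_spec")
})

test_that("ideal scanner voxelization yields two plateaus plus boundary", {
  box <- box_mesh(c(0.3, 0.3, 0.3), c(3.3, 3.3, 3.3))
  dev <- device_model("ideal", hu_air = -800, hu_stone = 5050,
                      psf_sigma_mm = 0, noise_sd_hu = 0, voxel_mm = 0.3)
  vol <- voxelize(box, dev)
  v <- as.vector(vol$values)
  expect_true(all(v >= dev$hu_air - 1e-9 & v <= dev$hu_stone + 1e-9))
  # away from the surface only the two plateaus appear; the mixed
  # (partial-volume) voxels form a single boundary shell
  n_mixed <- sum(v > dev$hu_air + 1e-6 & v < dev$hu_stone - 1e-6)
  side_vox <- 3 / 0.3
  expect_lt(n_mixed, 6 * (side_vox + 2)^2 * 2) # within ~2 boundary layers
  expect_gt(sum(abs(v - dev$hu_stone) < 1e-6), 0.5 * side_vox^3)
})

test_that("voxelization is deterministic given the seed", {
  m <- micro_sphere()
  dev <- device_model("n", psf_sigma_mm = 0.2, noise_sd_hu = 100,
                      voxel_mm = 0.4)
  v1 <- voxelize(m, dev, seed = 9)
  v2 <- voxelize(m, dev, seed = 9)
  v3 <- voxelize(m, dev, seed = 10)
  expect_identical(v1$values, v2$values)
  expect_false(identical(v1$values, v3$values))
})

test_that("voxelize rejects open meshes and honors the HU scale", {
  open_mesh <- tri_mesh(matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3,
                               byrow = TRUE), matrix(c(1, 2, 3), 1))
  dev <- device_model("d", voxel_mm = 0.3)
  expect_error(voxelize(open_mesh, dev), class = "mf_open_mesh")
  noisy <- device_model("n2", hu_air = -800, hu_stone = 5050,
                        psf_sigma_mm = 0.1, noise_sd_hu = 2000,
                        voxel_mm = 0.4)
  vol <- voxelize(micro_sphere(), noisy, seed = 1)
  expect_gte(min(vol$values), -1000)
  expect_lte(max(vol$values), 7000)
})

test_that("with symmetric blur the midpoint iso-surface tracks the truth", {
  # sphere phantom, no noise: surface at (hu_air + hu_stone)/2 within
  # half a voxel of the true radius
  vol <- sphere_volume(r = 4, vx = 0.2, mode = "pv")
  dev_sigma <- 0.3
  blurred <- meshfidelity:::.gaussian_blur3(
    as.numeric(vol$values), dim(vol$values), rep(dev_sigma / 0.2, 3))
  volb <- voxel_volume(array(blurred, dim(vol$values)), vol$spacing_mm,
                       vol$origin_mm)
  m <- extract_mesh(volb, 1000) # midpoint of -1000/3000
  rad <- sqrt(rowSums(m$vertices^2))
  expect_lt(max(abs(rad - 4)), 0.1) # half a voxel
})

test_that("noise degrades the optimal-threshold deviation monotonically", {
  gt <- micro_sphere()
  meds <- vapply(c(0, 400, 1200), function(ns) {
    dev <- device_model("n", hu_air = -800, hu_stone = 5050,
                        psf_sigma_mm = 0.2, noise_sd_hu = ns, voxel_mm = 0.4)
    med <- vapply(1:3, function(s) {
      vol <- voxelize(gt, dev, seed = s)
      m <- extract_mesh(vol, (dev$hu_air + dev$hu_stone) / 2)
      median(face_deviations(m, gt))
    }, numeric(1))
    mean(med)
  }, numeric(1))
  expect_true(all(diff(meds) > -1e-4)) # non-decreasing up to tolerance
})

test_that("HU offset shifts the DI-minimizing threshold equivariantly", {
  gt <- micro_sphere()
  levels <- seq(1425, 2625, by = 100)
  best_of <- function(offset) {
    dev <- device_model("o", hu_air = -800, hu_stone = 5050,
                        psf_sigma_mm = 0.25, noise_sd_hu = 60,
                        hu_offset = offset, voxel_mm = 0.4)
    vol <- voxelize(gt, dev, seed = 4)
    di <- vapply(levels, function(lv) {
      s <- summarize_deviations(face_deviations(extract_mesh(vol, lv), gt))
      s$di
    }, numeric(1))
    levels[which.min(di)]
  }
  b0 <- best_of(0)
  b300 <- best_of(300)
  expect_lte(abs((b300 - b0) - 300), 100) # within one sweep step
})
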