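test_that("rigid transforms compose, invert and validate", {
  set.seed(1)
  a <- random_rigid(c(5, 20), c(1, 3))
  b <- random_rigid(c(5, 20), c(1, 3))
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(rt_apply(rt_compose(a, b), p),
               rt_apply(a, rt_apply(b, p)), tolerance = 1e-12)
  roundtrip <- rt_compose(rt_invert(a), a)
  expect_equal(rt_magnitude(roundtrip)[["angle_rad"]], 0, tolerance = 1e-9)
  expect_error(rigid_transform(matrix(1, 3, 3)),
               class = "mf_invalid_transform")
})

test_that("coarse registration is exact on noiseless correspondences", {
  set.seed(2)
  src <- matrix(rnorm(15, sd = 5), 5, 3)
  ident <- coarse_register(src, src)
  expect_equal(ident$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(ident$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(ident$rms, 0, tolerance = 1e-12)

  truth <- random_rigid(c(10, 30), c(1, 5))
  fit <- coarse_register(src, rt_apply(truth, src))
  expect_lt(max(abs(fit$transform$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(fit$transform$translation - truth$translation)), 1e-9)
})

test_that("coarse registration matches the quaternion oracle", {
  set.seed(3)
  for (trial in 1:20) {
    src <- matrix(rnorm(15, sd = 3), 5, 3)
    dst <- rt_apply(random_rigid(c(1, 40), c(0.1, 4)), src) +
      matrix(rnorm(15, sd = 0.05), 5, 3)
    fit <- coarse_register(src, dst)
    oracle <- horn_fit(src, dst)
    expect_lt(max(abs(fit$transform$rotation - oracle$rotation)), 1e-9)
    expect_lt(max(abs(fit$transform$translation - oracle$translation)), 1e-9)
  }
})

test_that("noisy correspondences give sigma-order residuals", {
  set.seed(4)
  src <- matrix(rnorm(150, sd = 5), 50, 3)
  truth <- random_rigid(c(5, 15), c(0.5, 2))
  rms <- replicate(20, {
    dst <- rt_apply(truth, src) + matrix(rnorm(150, sd = 0.01), 50, 3)
    fit <- coarse_register(src, dst)
    expect_lt(max(abs(fit$transform$rotation - truth$rotation)), 1e-2)
    fit$rms
  })
  expect_lt(abs(mean(rms) - 0.01), 0.01) # sigma order
})

test_that("degenerate point configurations are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(coarse_register(line, line + 1),
               class = "mf_degenerate_points")
  same <- matrix(1, 4, 3)
  expect_error(coarse_register(same, same), class = "mf_degenerate_points")
  expect_error(coarse_register(line[1:2, ], line[1:2, ]),
               class = "mf_degenerate_points")
})

test_that("ICP recovers a known displacement of a phantom mesh", {
  gt <- tiny_phantom()
  set.seed(5)
  # the protocol-scale perturbation: 0.5 mm / 3 degrees about z
  ang <- 3 * pi / 180
  pert <- rigid_transform(rbind(c(cos(ang), -sin(ang), 0),
                                c(sin(ang), cos(ang), 0),
                                c(0, 0, 1)), c(0.5, 0, 0))
  moved <- rt_apply_mesh(pert, gt)
  reg <- icp_register(moved, gt, icp_config(n_sample_pairs = 3000,
                                            rng_seed = 6,
                                            max_iterations = 400,
                                            convergence_tol_mm = 1e-9))
  resid <- rt_magnitude(rt_compose(reg$transform, pert))
  expect_lt(resid[["angle_rad"]], 1e-3)
  expect_lt(resid[["translation_mm"]], 1e-3)
  expect_lt(reg$final_rms, 1e-3)
  # sampled RMS is non-increasing across iterations
  expect_true(all(diff(reg$rms_trace) <= 1e-12))
})

test_that("ICP on identical meshes is the identity, deterministically", {
  m <- micro_sphere()
  r1 <- icp_register(m, m, icp_config(n_sample_pairs = 1000, rng_seed = 3))
  r2 <- icp_register(m, m, icp_config(n_sample_pairs = 1000, rng_seed = 3))
  expect_identical(r1$transform, r2$transform)
  expect_identical(r1$rms_trace, r2$rms_trace)
  expect_lt(rt_magnitude(r1$transform)[["angle_rad"]], 1e-9)
  expect_lt(r1$final_rms, 1e-9)
})

test_that("non-overlapping meshes fail registration with a guard error", {
  m <- micro_sphere()
  far <- rt_apply_mesh(rigid_transform(diag(3), c(500, 0, 0)), m)
  expect_error(icp_register(far, m, icp_config(n_sample_pairs = 500)),
               class = "mf_registration_failure")
})

test_that("the clone-perturb-register self-test reports sub-micron error", {
  gt <- tiny_phantom()
  st <- software_self_test(gt, n_trials = 3, seed = 11,
                           cfg = icp_config(n_sample_pairs = 3000,
                                            max_iterations = 60))
  # order of magnitude acceptance, mirroring the published figure
  expect_lt(st$mean_error_mm, 1e-3)
  st2 <- software_self_test(gt, n_trials = 3, seed = 11,
                            cfg = icp_config(n_sample_pairs = 3000,
                                             max_iterations = 60))
  expect_identical(st$trial_means_mm, st2$trial_means_mm)
})
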