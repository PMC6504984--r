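test_that("one-way RM-ANOVA matches the from-scratch oracle", {
  set.seed(10)
  for (trial in 1:5) {
    n <- sample(3:5, 1)
    k <- sample(3:4, 1)
    Y <- matrix(rnorm(n * k, mean = rep(seq_len(k), each = n)), n, k)
    res <- rm_anova_oneway(Y)$anova
    oracle <- rm_oneway_oracle(Y)
    expect_equal(res$F, oracle$F, tolerance = 1e-10)
    expect_equal(res$ss_condition, oracle$ss_cond, tolerance = 1e-10)
    # SS conservation
    expect_equal(res$ss_total,
                 res$ss_condition + res$ss_subject + res$ss_residual,
                 tolerance = 1e-9)
    # cross-check against the standard within-subject aov fit
    df <- data.frame(y = as.vector(Y), s = factor(rep(seq_len(n), k)),
                     c = factor(rep(seq_len(k), each = n)))
    fit <- summary(stats::aov(y ~ c + Error(s / c), data = df))
    f_aov <- fit[["Error: s:c"]][[1]]["c", "F value"]
    expect_equal(res$F, f_aov, tolerance = 1e-10)
  }
})

test_that("constant responses give F = 0 and null pairwise differences", {
  Y <- matrix(2, 5, 3)
  res <- rm_anova_oneway(Y)
  expect_equal(res$anova$F, 0)
  expect_true(all(res$pairwise$mean_difference == 0))
  expect_true(all(res$pairwise$p_sidak == 1))
})

test_that("a two-condition design reduces to the paired t-test", {
  set.seed(11)
  Y <- matrix(rnorm(20, mean = rep(c(0, 0.5), each = 10)), 10, 2)
  res <- rm_anova_oneway(Y)
  tt <- stats::t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(res$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$anova$p_uncorrected, tt$p.value, tolerance = 1e-10)
})

test_that("design errors are raised", {
  expect_error(rm_anova_oneway(matrix(1, 1, 3)), class = "mf_design_error")
  expect_error(rm_anova_oneway(matrix(1, 5, 1)), class = "mf_design_error")
  expect_error(rm_anova_twoway(array(1, c(5, 3))), class = "mf_design_error")
})

test_that("Sidak adjustment follows the closed form and is monotone", {
  expect_equal(sidak_adjust(0.02, 3), 1 - (1 - 0.02)^3, tolerance = 1e-15)
  expect_equal(sidak_adjust(0.02, 3), 0.058808, tolerance = 1e-6)
  p <- seq(0.001, 0.9, length.out = 50)
  for (m in c(2, 3, 6)) {
    expect_true(all(diff(sidak_adjust(p, m)) > 0))
    expect_true(all(sidak_adjust(p, m) >= p))
    expect_true(all(sidak_adjust(p, m + 1) >= sidak_adjust(p, m)))
  }
})

test_that("two-way RM-ANOVA reproduces the frozen reference fixture", {
  # expected values computed once with an independent implementation
  # (pingouin 0.6.1) on this exact seed-42 fixture
  set.seed(42)
  n <- 6; a <- 3; b <- 4
  Y <- array(rnorm(n * a * b, mean = rep(1:a, each = n), sd = 1) +
               rep(seq(0, 1.5, length.out = b), each = n * a), c(n, a, b))
  res <- rm_anova_twoway(Y)
  expect_equal(res$F[res$effect == "A"], 23.136195, tolerance = 1e-5)
  expect_equal(res$gg_epsilon[res$effect == "A"], 0.6778151, tolerance = 1e-6)
  expect_equal(res$p_gg[res$effect == "A"], 0.001472724, tolerance = 1e-6)
  expect_equal(res$F[res$effect == "B"], 4.133635, tolerance = 1e-5)
  expect_equal(res$gg_epsilon[res$effect == "B"], 0.8134014, tolerance = 1e-6)
  expect_equal(res$p_gg[res$effect == "B"], 0.036635637, tolerance = 1e-6)
  expect_equal(res$F[res$effect == "A:B"], 2.035797, tolerance = 1e-5)
  expect_equal(res$p_uncorrected[res$effect == "A:B"], 0.0916226,
               tolerance = 1e-5)
})

test_that("an additive response has zero interaction", {
  n <- 5; a <- 3; b <- 4
  subj <- rnorm(n)
  Y <- array(0, c(n, a, b))
  for (i in 1:a) for (j in 1:b) Y[, i, j] <- subj + i * 0.5 + j * 0.2
  res <- rm_anova_twoway(Y)
  expect_equal(res$F[res$effect == "A:B"], 0)
  expect_gt(res$F[res$effect == "A"], 0)
})

test_that("2x2 effects equal the squared paired t of their contrasts", {
  set.seed(12)
  n <- 8
  Y <- array(rnorm(n * 4, mean = rep(c(0, 0.6, 0.3, 1.4), each = n)),
             c(n, 2, 2))
  res <- rm_anova_twoway(Y)
  t_a <- stats::t.test(rowMeans(Y[, 1, ]), rowMeans(Y[, 2, ]),
                       paired = TRUE)$statistic
  t_b <- stats::t.test(rowMeans(Y[, , 1]), rowMeans(Y[, , 2]),
                       paired = TRUE)$statistic
  t_ab <- stats::t.test(Y[, 1, 1] - Y[, 2, 1] - Y[, 1, 2] + Y[, 2, 2])$statistic
  expect_equal(res$F[res$effect == "A"], unname(t_a)^2, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "B"], unname(t_b)^2, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "A:B"], unname(t_ab)^2, tolerance = 1e-10)
})

test_that("epsilon is 1 under compound symmetry and bounded otherwise", {
  C <- meshfidelity:::orth_contrasts(4)
  cs <- diag(4) * 0.7 + 0.3 # compound-symmetric covariance
  expect_equal(meshfidelity:::gg_epsilon_cov(cs, C), 1, tolerance = 1e-12)
  set.seed(13)
  for (trial in 1:20) {
    A <- matrix(rnorm(16), 4, 4)
    S <- crossprod(A) + diag(4) * 0.01
    e <- meshfidelity:::gg_epsilon_cov(S, C)
    expect_gte(e, 1 / 3)
    expect_lte(e, 1)
  }
})

test_that("simple main effects match an exact sign-flip permutation oracle", {
  set.seed(14)
  n <- 10
  Y <- array(rnorm(n * 3 * 2, sd = 0.05), c(n, 3, 2))
  Y[, 3, 1] <- Y[, 3, 1] + 1 # one shifted modality at level 1 only
  sme <- simple_main_effects(Y, names_a = c("m1", "m2", "m3"),
                             names_b = c("t1", "t2"))
  perm_p <- function(d) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(d))))
    stat <- abs(signs %*% d) / length(d)
    mean(stat >= abs(mean(d)) - 1e-12)
  }
  for (row in seq_len(nrow(sme))) {
    lv <- match(sme$level[row], c("t1", "t2"))
    pr <- strsplit(sme$pair[row], "-")[[1]]
    ia <- match(pr, c("m1", "m2", "m3"))
    p_oracle <- sidak_adjust(perm_p(Y[, ia[1], lv] - Y[, ia[2], lv]), 3)
    expect_identical(sme$p_sidak[row] < 0.05, p_oracle < 0.05)
    shifted <- (3 %in% ia) && lv == 1L
    expect_identical(sme$p_sidak[row] < 0.05, shifted)
  }
  # equal responses at a level: all adjusted p are 1
  Yc <- array(rep(1:10, 6), c(n, 3, 2))
  smec <- simple_main_effects(Yc)
  expect_true(all(smec$p_sidak == 1))
  expect_error(simple_main_effects(Y, at = "t9"), class = "mf_unknown_level")
})

test_that("repeatability enumerates all ordered pairs", {
  m <- micro_sphere()
  rep10 <- repeatability(rep(list(m), 4),
                         cfg = icp_config(n_sample_pairs = 500),
                         register = FALSE)
  expect_identical(rep10$n_pairs, 12L) # n (n - 1)
  expect_equal(rep10$mean_diff_mm, 0, tolerance = 1e-12)
  expect_equal(rep10$mean_sd_mm, 0, tolerance = 1e-12)
  expect_error(repeatability(list(m)), class = "mf_design_error")
})

test_that("repeatability degrades monotonically with rescan noise", {
  gt <- micro_sphere()
  sd_of <- function(ns) {
    dev <- device_model("r", hu_air = -800, hu_stone = 5050,
                        psf_sigma_mm = 0.2, noise_sd_hu = ns, voxel_mm = 0.4)
    scans <- lapply(1:3, function(s)
      extract_mesh(voxelize(gt, dev, seed = 20 + s), 2125))
    repeatability(scans, register = FALSE)$mean_sd_mm
  }
  sds <- vapply(c(50, 400, 1200), sd_of, numeric(1))
  expect_true(all(diff(sds) > 0))
})
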