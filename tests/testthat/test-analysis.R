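test_that("PCA spectrum matches a direct covariance oracle", {
  set.seed(101)
  X <- matrix(rnorm(15 * 6), 15, 6)  # 15 neurons x 6 conditions
  res <- pca_contributions(X)
  # independent oracle: full covariance of neurons over conditions
  oracle <- eigen(stats::cov(t(X)), symmetric = TRUE, only.values = TRUE)$values
  oracle <- oracle[oracle > 1e-12]
  expect_equal(res$eigenvalues[seq_along(oracle)], oracle, tolerance = 1e-8)
  expect_equal(sum(res$contributions), 100, tolerance = 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
})

test_that("two orthogonal equal-power patterns split 50/50", {
  base <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  # conditions alternate between +/- each pattern: equal power, zero mean
  X <- cbind(base[, 1], -base[, 1], base[, 2], -base[, 2])
  res <- pca_contributions(X)
  expect_equal(res$contributions[1:2], c(50, 50), tolerance = 1e-8)
  expect_equal(res$n_nonzero, 2L)
})

test_that("nonzero eigenvalue count is bounded by conditions and neurons", {
  geo <- task_geometry()
  for (theta in c(3, -1)) {
    cod <- coding_layer(sensory_weights(100, seed = 5),
                        threshold_spec(theta, 100))
    res <- pca_contributions(activity_matrix(cod, geo))
    expect_lte(res$n_nonzero, 24)
    expect_false(res$degenerate)
  }
  # degenerate: constant patterns
  res0 <- pca_contributions(matrix(1, 5, 4))
  expect_true(res0$degenerate)
  expect_equal(res0$n_nonzero, 0L)
})

test_that("generalization error is exact for L = 1 and consistent", {
  geo <- small_geometry()
  cod <- small_coding(20, theta = 0.2, seed = 111)
  fit <- train(geo, cod, learning_params(n_trials = 3000), seed = 7)
  g1 <- generalization_error(fit, cod, geo, L = 1, seed = 12)
  # oracle: recompute the single target's mean error over postures
  ang <- sparsemotor:::with_seed(12L, stats::runif(1, 0, 2 * pi))
  v <- c(cos(ang), sin(ang))
  errs <- vapply(seq_len(geo$postures$count), function(kp) {
    A <- compute_activity(cod, v, geo$postures$vectors[, kp])$values
    M <- pmax(as.vector(fit$W %*% A), 0)
    sum((v - as.vector(geo$muscles$projections[, , kp] %*% M))^2)
  }, numeric(1))
  expect_equal(g1, mean(errs), tolerance = 1e-12)

  # evenly spaced novel targets supported
  ge <- generalization_error(fit, cod, geo, L = 16, method = "even")
  expect_true(is.finite(ge) && ge >= 0)
})

test_that("tuning matrices replicate compute_activity per condition", {
  geo <- small_geometry(K = 4, n_post = 2)
  cod <- small_coding(9, theta = 0.5, seed = 121)
  tm <- tuning_matrix(3, cod, geo)
  expect_equal(dim(tm), c(4, 2))
  for (kp in 1:2) {
    for (k in 1:4) {
      a <- compute_activity(cod, geo$targets$vectors[, k],
                            geo$postures$vectors[, kp])
      expect_equal(tm[k, kp], a$values[3], ignore_attr = TRUE,
                   tolerance = 1e-12)
    }
  }
  expect_error(tuning_matrix(10, cod, geo), "out of range")
  silent_cod <- small_coding(9, theta = 1e3, seed = 121)
  expect_true(all(tuning_matrix(1, silent_cod, geo) == 0))
})

test_that("modulation fit separates additive and multiplicative tables", {
  # additive table with strong crossed contrasts (a near-constant additive
  # table is itself near rank-1, which the margin rule calls ambiguous)
  add <- outer(c(0, 1, 0, 1), c(1, 0, 1), "+")
  mul <- outer(c(0.2, 1, 0.4, 0.8), c(0.3, 0.9, 0.5))
  fit_add <- modulation_fit(add)
  expect_equal(fit_add$r2_additive, 1, tolerance = 1e-10)
  expect_equal(fit_add$classification, "additive")
  fit_mul <- modulation_fit(mul)
  expect_equal(fit_mul$r2_multiplicative, 1, tolerance = 1e-8)
  expect_equal(fit_mul$classification, "multiplicative")
  expect_equal(modulation_fit(matrix(0, 4, 3))$classification, "flat")
})

test_that("modulation classification is scale invariant", {
  set.seed(131)
  for (i in 1:10) {
    tm <- matrix(abs(rnorm(12)), 4, 3)
    f1 <- modulation_fit(tm)
    f2 <- modulation_fit(tm * runif(1, 0.5, 50))
    expect_equal(f1$classification, f2$classification)
  }
})

test_that("theta sweeps are reproducible and locate trivial argmins", {
  geo <- small_geometry()
  p <- learning_params(n_trials = 800)
  sw <- theta_sweep(grid = c(-1, 0.5, 1.5), runs = 2, geometry = geo,
                    n_neurons = 40, params = p, seed = 19)
  sw2 <- theta_sweep(grid = c(-1, 0.5, 1.5), runs = 2, geometry = geo,
                     n_neurons = 40, params = p, seed = 19)
  expect_identical(sw$mean_error, sw2$mean_error)
  expect_identical(sw$sparseness, sw2$sparseness)
  expect_true(all(sw$sd_error >= 0))

  single <- theta_sweep(grid = 0.5, runs = 1, geometry = geo,
                        n_neurons = 40, params = p, seed = 19)
  expect_equal(single$opt_theta, 0.5)
})
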