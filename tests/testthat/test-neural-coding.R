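test_that("sensory weights are reproducible standard Gaussians", {
  w <- sensory_weights(2000, seed = 8)
  expect_equal(dim(w$J_v), c(2000, 2))
  expect_equal(dim(w$J_p), c(2000, 2))
  draws <- c(w$J_v, w$J_p)
  expect_lt(abs(mean(draws)), 0.05)
  expect_lt(abs(sd(draws) - 1), 0.05)
  expect_identical(w, sensory_weights(2000, seed = 8))
  expect_error(sensory_weights(0), "positive integer")
})

test_that("heterogeneous thresholds jitter around the base value", {
  th <- threshold_spec(3, 5000, heterogeneity_sd = 0.1, seed = 2)
  expect_lt(abs(mean(th$values) - 3), 0.01)
  expect_lt(abs(sd(th$values) - 0.1), 0.01)
  expect_equal(threshold_spec(3, 10)$values, rep(3, 10))
})

test_that("activity matches the hand evaluation and naive oracle", {
  cod <- manual_coding(rbind(c(1, 0), c(0, 1), c(-1, 0)),
                       matrix(0, 3, 2), theta = 0)
  a <- compute_activity(cod, c(1, 0), c(0, 1))
  expect_equal(a$values, c(1, 0, 0), tolerance = 1e-12)
  expect_false(a$is_silent)

  # naive per-neuron loop oracle on random small instances
  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    cod <- small_coding(n, theta = runif(1, -1, 2), seed = i)
    v <- as.vector(uv(runif(1, 0, 2 * pi)))
    p <- as.vector(uv(runif(1, 0, 2 * pi)))
    a <- compute_activity(cod, v, p)
    r <- numeric(n)
    for (j in seq_len(n)) {
      u <- sum(cod$weights$J_v[j, ] * v) + sum(cod$weights$J_p[j, ] * p) -
        cod$thresholds$values[j]
      r[j] <- max(u, 0)
    }
    expected <- if (all(r == 0)) r else r / sqrt(sum(r^2))
    expect_equal(a$values, expected, tolerance = 1e-12)
  }
})

test_that("activity is silent above the maximal drive and unit when one fires", {
  cod <- small_coding(6, theta = 1e3, seed = 4)
  a <- compute_activity(cod, c(1, 0), c(0, 1))
  expect_true(a$is_silent)
  expect_equal(a$values, rep(0, 6))

  # exactly one neuron above threshold gets activity 1 after normalization
  cod <- manual_coding(rbind(c(1, 0), c(-1, 0)), matrix(0, 2, 2), theta = 0.5)
  a <- compute_activity(cod, c(1, 0), c(0, 1))
  expect_equal(a$values, c(1, 0))
})

test_that("non-silent activities carry unit metabolic cost", {
  geo <- small_geometry()
  set.seed(5)
  for (kind in c("threshold_linear", "tanh_rectified", "sigmoid",
                 "tanh_positive")) {
    cod <- small_coding(12, theta = 0.8, seed = 6,
                        activation = activation_spec(kind))
    A <- activity_matrix(cod, geo)
    silent <- attr(A, "silent")
    nrm2 <- colSums(A^2)
    expect_true(all(abs(nrm2[!silent] - 1) < 1e-10))
    expect_true(all(A[, silent] == 0))
    expect_true(all(A >= 0))
  }
})

test_that("activity matrix agrees with per-condition computation", {
  geo <- small_geometry(K = 3, n_post = 2)
  cod <- small_coding(7, theta = 0.3, seed = 9)
  A <- activity_matrix(cod, geo)
  expect_equal(dim(A), c(7, 6))
  for (kp in 1:2) {
    for (k in 1:3) {
      a <- compute_activity(cod, geo$targets$vectors[, k],
                            geo$postures$vectors[, kp])
      expect_equal(A[, (kp - 1) * 3 + k], a$values,
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("sparseness hits its extremes and is monotone in theta", {
  geo <- small_geometry()
  w <- sensory_weights(40, seed = 12)
  lo <- coding_layer(w, threshold_spec(-50, 40))
  hi <- coding_layer(w, threshold_spec(50, 40))
  expect_equal(sparseness(lo, geo), 0)
  expect_equal(sparseness(hi, geo), 1)
  grid <- seq(-3, 3.8, length.out = 18)
  sp <- vapply(grid, function(th) {
    sparseness(coding_layer(w, threshold_spec(th, 40)), geo)
  }, numeric(1))
  expect_true(all(diff(sp) >= 0))
})
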