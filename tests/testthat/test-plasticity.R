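test_that("muscle activity rectifies the drive", {
  W <- matrix(0, 3, 4)
  res <- muscle_activity(W, rep(0.5, 4))
  expect_equal(res$M, rep(0, 3))
  expect_false(any(res$active))

  W <- rbind(c(1, -1), c(0, 2))
  res <- muscle_activity(W, c(0.6, 0.8))
  expect_equal(res$M, c(0, 1.6))  # row 1 drive -0.2 rectified away
  expect_equal(res$active, c(FALSE, TRUE))
})

test_that("masked projection zeroes exactly the inactive columns", {
  P <- uv(c(0, 1, 2))
  expect_equal(masked_projection(P, c(TRUE, TRUE, TRUE)), P)
  expect_equal(masked_projection(P, c(FALSE, FALSE, FALSE)), 0 * P)
  single <- masked_projection(P, c(FALSE, TRUE, FALSE))
  expect_equal(single[, 2], P[, 2])
  expect_equal(single[, c(1, 3)], 0 * P[, c(1, 3)])
})

test_that("update_W is a no-op without error or activity", {
  set.seed(31)
  inst <- random_muscle_instance()
  expect_equal(update_W(inst$W, c(0, 0), inst$A, inst$P, eta = 0.4), inst$W)
  expect_equal(update_W(inst$W, c(0.3, -1), 0 * inst$A, inst$P), inst$W)
})

test_that("update_W matches the finite-difference gradient oracle", {
  # >= 100 random kink-free instances, with and without muscle cost
  set.seed(32)
  worst <- 0
  for (i in 1:100) {
    lambda <- if (i %% 2 == 0) 0 else runif(1, 0, 0.5)
    inst <- random_muscle_instance()
    cost <- function(Wvec) {
      W <- matrix(Wvec, nrow(inst$W))
      M <- pmax(as.vector(W %*% inst$A), 0)
      0.5 * sum((inst$v - as.vector(inst$P %*% M))^2) +
        0.5 * lambda * sum(M^2)
    }
    num <- matrix(finite_difference_gradient(cost, as.vector(inst$W)),
                  nrow(inst$W))
    M <- pmax(inst$drive, 0)
    e <- inst$v - as.vector(inst$P %*% M)
    P_plus <- masked_projection(inst$P, inst$drive >= 0)
    eta <- 0.4
    delta <- update_W(inst$W, e, inst$A, P_plus, eta, lambda, M) - inst$W
    rel <- max(abs(delta / eta + num)) / max(abs(num), 1e-8)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("converged_error averages the requested window", {
  expect_equal(converged_error(rep(2.5, 100)), 2.5)
  expect_equal(converged_error(1:100, window = c(0.99, 1)), 100)
  set.seed(33)
  trace <- runif(1000)
  expect_equal(converged_error(trace, c(0.9, 1)),
               mean(trace[901:1000]), tolerance = 1e-12)
})

test_that("training without learning keeps the unit error baseline", {
  geo <- small_geometry()
  cod <- small_coding(10, theta = 0, seed = 41)
  fit <- train(geo, cod, learning_params(eta = 0, n_trials = 200), seed = 2)
  expect_true(all(fit$W == 0))
  expect_equal(fit$error, rep(1, 200))
})

test_that("silent networks never learn", {
  geo <- small_geometry()
  cod <- small_coding(10, theta = 1e3, seed = 41)
  fit <- train(geo, cod, learning_params(n_trials = 200), seed = 2)
  expect_true(all(fit$W == 0))
  expect_equal(fit$error, rep(1, 200))
})

test_that("factored and direct trainers are equivalent", {
  geo <- small_geometry()
  for (theta in c(-1, 0.5, 1.5)) {
    cod <- small_coding(30, theta = theta, seed = 51)
    p <- learning_params(n_trials = 1500)
    fa <- train(geo, cod, p, seed = 5, method = "factored")
    di <- train(geo, cod, p, seed = 5, method = "direct")
    expect_equal(fa$error, di$error, tolerance = 1e-10)
    expect_equal(fa$W, di$W, tolerance = 1e-10)
  }
})

test_that("training is deterministic given the seed", {
  geo <- small_geometry()
  cod <- small_coding(20, theta = 0.5, seed = 61)
  p <- learning_params(n_trials = 500)
  f1 <- train(geo, cod, p, seed = 77)
  f2 <- train(geo, cod, p, seed = 77)
  expect_identical(f1$error, f2$error)
  expect_identical(f1$W, f2$W)
})

test_that("learning reduces the error below the no-learning baseline", {
  geo <- task_geometry()
  cod <- coding_layer(sensory_weights(300, seed = 71),
                      threshold_spec(1.5, 300))
  fit <- train(geo, cod, learning_params(n_trials = 5000), seed = 6)
  expect_lt(fit$converged_error, 1)
  expect_lt(fit$converged_error, mean(fit$error[1:100]))
})
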