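#' Fixed random sensory weights
#'
#' Each neuron receives the visual target `v` through a weight row of
#' `J_v` and the proprioceptive posture `p` through a row of `J_p`.
#' Entries are iid standard Gaussian and stay fixed during learning in
#' the threshold-linear model.
#'
#' @param n_neurons number of neurons `N`.
#' @param seed RNG seed.
#' @param sd entry standard deviation (default 1); `sd = 0` gives the
#'   all-zero initial weights of the adaptable-J comparison networks.
#' @return An object of class `sensory_weights` with `J_v`, `J_p`
#'   (`N` x 2 matrices), `n_neurons` and `seed`.
#' @export
sensory_weights <- function(n_neurons, seed = 1L, sd = 1) {
  abort_if(!is_count(n_neurons) || n_neurons < 1,
           "`n_neurons` must be a positive integer")
  abort_if(!is_scalar(sd) || sd < 0, "`sd` must be a nonnegative scalar")
  mats <- with_seed(seed, list(
    J_v = matrix(stats::rnorm(n_neurons * 2, 0, sd), n_neurons, 2),
    J_p = matrix(stats::rnorm(n_neurons * 2, 0, sd), n_neurons, 2)))
  structure(list(J_v = mats$J_v, J_p = mats$J_p,
                 n_neurons = as.integer(n_neurons), seed = as.integer(seed)),
            class = "sensory_weights")
}

#' Neuron firing thresholds
#'
#' The threshold `theta` is the single knob controlling coding
#' sparseness: low thresholds leave most neurons active for every input
#' (dense coding), high thresholds silence most of the population
#' (sparse coding).  Heterogeneous thresholds add Gaussian jitter
#' `theta_i = theta + xi_i` with `xi_i ~ N(0, heterogeneity_sd)`.
#'
#' @param theta base threshold (scalar).
#' @param n_neurons number of neurons.
#' @param heterogeneity_sd standard deviation of the per-neuron jitter;
#'   0 (default) gives a homogeneous threshold.
#' @param seed RNG seed for the jitter.
#' @return An object of class `threshold_spec` with per-neuron `values`.
#' @export
threshold_spec <- function(theta, n_neurons, heterogeneity_sd = 0,
                           seed = 1L) {
  abort_if(!is_scalar(theta), "`theta` must be a finite scalar")
  abort_if(!is_count(n_neurons) || n_neurons < 1,
           "`n_neurons` must be a positive integer")
  abort_if(!is_scalar(heterogeneity_sd) || heterogeneity_sd < 0,
           "`heterogeneity_sd` must be a nonnegative scalar")
  values <- if (heterogeneity_sd > 0) {
    theta + with_seed(seed, stats::rnorm(n_neurons, 0, heterogeneity_sd))
  } else {
    rep(theta, n_neurons)
  }
  structure(list(theta = theta, heterogeneity_sd = heterogeneity_sd,
                 n_neurons = as.integer(n_neurons), seed = as.integer(seed),
                 values = values),
            class = "threshold_spec")
}

#' Activation nonlinearity
#'
#' @param kind one of
#'   * `"threshold_linear"`: rectified linear, `r = max(u, 0)` (default);
#'   * `"tanh_rectified"`: `r = max(tanh(beta * u), 0)`;
#'   * `"sigmoid"`: logistic re-zeroed at the threshold and rectified,
#'     `r = max(plogis(beta * u) - 0.5, 0)`;
#'   * `"tanh_positive"`: `r = (1 + tanh(beta * u)) / 2`, smooth and
#'     strictly positive -- used by the comparison networks whose sensory
#'     weights start at zero and must produce nonzero activity there.
#' @param beta slope of the saturating nonlinearities; ignored by
#'   `"threshold_linear"`.
#' @return An object of class `activation_spec`.
#' @export
activation_spec <- function(kind = c("threshold_linear", "tanh_rectified",
                                     "sigmoid", "tanh_positive"),
                            beta = 1) {
  kind <- match.arg(kind)
  abort_if(!is_scalar(beta) || beta <= 0, "`beta` must be a positive scalar")
  structure(list(kind = kind, beta = beta), class = "activation_spec")
}

# Raw (pre-normalization) activity from a matrix of pre-activations
# u = J_v v + J_p p - theta.  Works columnwise on an N x C matrix.
apply_activation <- function(u, activation) {
  switch(activation$kind,
    threshold_linear = pmax(u, 0),
    tanh_rectified   = pmax(tanh(activation$beta * u), 0),
    sigmoid          = pmax(stats::plogis(activation$beta * u) - 0.5, 0),
    tanh_positive    = (1 + tanh(activation$beta * u)) / 2)
}

#' Coding layer: weights, thresholds and activation
#'
#' Bundles everything needed to turn a (target, posture) input pair into
#' a population activity vector with unit squared norm (fixed metabolic
#' cost).
#'
#' @param weights a [sensory_weights()].
#' @param thresholds a [threshold_spec()] of matching size.
#' @param activation an [activation_spec()].
#' @return An object of class `coding_layer`.
#' @export
coding_layer <- function(weights, thresholds,
                         activation = activation_spec()) {
  abort_if(!inherits(weights, "sensory_weights"),
           "`weights` must be a sensory_weights object")
  abort_if(!inherits(thresholds, "threshold_spec"),
           "`thresholds` must be a threshold_spec object")
  abort_if(!inherits(activation, "activation_spec"),
           "`activation` must be an activation_spec object")
  abort_if(weights$n_neurons != thresholds$n_neurons,
           "weights and thresholds disagree on the number of neurons")
  structure(list(weights = weights, thresholds = thresholds,
                 activation = activation,
                 n_neurons = weights$n_neurons),
            class = "coding_layer")
}

#' Population activity for one input pair
#'
#' Computes the pre-activation `u_i = J_v[i,] . v + J_p[i,] . p -
#' theta_i`, applies the activation nonlinearity, and normalizes the
#' population vector to unit squared norm so the metabolic cost
#' `t(A) %*% A = 1` is identical for every input and every threshold.
#' If no neuron responds the input is silent: the zero vector is
#' returned unnormalized and flagged.
#'
#' @param coding a [coding_layer()].
#' @param v visual target unit vector.
#' @param p posture unit vector.
#' @param tol tolerance for the unit-norm check on `v` and `p`.
#' @return An object of class `activity` with `values` (length `N`),
#'   logical `active` mask and `is_silent` flag.
#' @export
compute_activity <- function(coding, v, p, tol = 1e-8) {
  abort_if(!inherits(coding, "coding_layer"),
           "`coding` must be a coding_layer")
  check_unit(v, "v", tol)
  check_unit(p, "p", tol)
  u <- as.vector(coding$weights$J_v %*% v + coding$weights$J_p %*% p) -
    coding$thresholds$values
  r <- apply_activation(u, coding$activation)
  nrm2 <- sum(r * r)
  if (nrm2 == 0) {
    values <- r
    silent <- TRUE
  } else {
    values <- r / sqrt(nrm2)
    silent <- FALSE
  }
  structure(list(values = values, active = values > 0, is_silent = silent),
            class = "activity")
}

#' Activity pattern matrix over all task conditions
#'
#' Evaluates the coding layer on every (target, posture) pair of the
#' task, giving the `N` x `C` matrix (`C = K * postures`) that feeds the
#' sparseness measure, PCA and tuning analyses.  Columns are normalized
#' to unit squared norm per condition; silent conditions stay all-zero.
#'
#' @param coding a [coding_layer()].
#' @param geometry a [task_geometry()].
#' @return A numeric matrix with condition labels `"k_kp"` as column
#'   names and attribute `silent` marking all-zero conditions.
#' @export
activity_matrix <- function(coding, geometry) {
  abort_if(!inherits(geometry, "task_geometry"),
           "`geometry` must be a task_geometry")
  drive_v <- coding$weights$J_v %*% geometry$targets$vectors    # N x K
  drive_p <- coding$weights$J_p %*% geometry$postures$vectors   # N x n_post
  K <- geometry$targets$K
  n_post <- geometry$postures$count
  u <- matrix(NA_real_, coding$n_neurons, K * n_post)
  for (j in seq_len(n_post)) {
    u[, (j - 1L) * K + seq_len(K)] <- drive_v + drive_p[, j]
  }
  u <- u - coding$thresholds$values
  r <- apply_activation(u, coding$activation)
  nrm <- sqrt(colSums(r * r))
  silent <- nrm == 0
  nrm[silent] <- 1
  A <- sweep(r, 2, nrm, "/")
  colnames(A) <- condition_labels(geometry)
  attr(A, "silent") <- silent
  A
}

#' Coding sparseness
#'
#' Sparseness is `N_NA / N`: the fraction of neurons whose activity is
#' exactly zero for every (target, posture) input condition of the task.
#' It grows monotonically with the threshold `theta`.
#'
#' @param coding a [coding_layer()], or a precomputed activity matrix.
#' @param geometry a [task_geometry()] (ignored when `coding` is a
#'   matrix).
#' @return A fraction in `[0, 1]`.
#' @export
sparseness <- function(coding, geometry = task_geometry()) {
  A <- if (is.matrix(coding)) coding else activity_matrix(coding, geometry)
  abort_if(ncol(A) < 1, "activity matrix must have at least one condition")
  mean(apply(A, 1, function(row) all(row == 0)))
}
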