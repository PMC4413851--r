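#' Sweep the threshold and locate the error-optimal sparseness
#'
#' For each run one draw of the sensory weights is shared across the
#' whole threshold grid (so the grid compares coding regimes, not weight
#' draws); each (run, theta) network is trained from `W = 0` and its
#' converged movement error recorded, along with the coding sparseness
#' at that threshold.
#'
#' @param grid threshold values; default 18 linearly spaced points from
#'   -3 to 3.8.
#' @param runs number of independent sensory-weight draws (default 10).
#' @param geometry a [task_geometry()].
#' @param n_neurons population size (default 2000).
#' @param params a [learning_params()].
#' @param seed master seed; per-run weight and schedule seeds are
#'   spawned from it.
#' @param heterogeneity_sd per-neuron threshold jitter sd (0 =
#'   homogeneous).
#' @param activation an [activation_spec()].
#' @return An object of class `sweep_result` with `grid`, `mean_error`,
#'   `sd_error`, `sparseness` (averaged over runs), the per-run `errors`
#'   matrix (runs x grid), `opt_theta` (grid argmin of the mean error)
#'   and `opt_sparseness`.
#' @export
theta_sweep <- function(grid = seq(-3, 3.8, length.out = 18), runs = 10L,
                        geometry = task_geometry(), n_neurons = 2000L,
                        params = learning_params(), seed = 1L,
                        heterogeneity_sd = 0,
                        activation = activation_spec()) {
  abort_if(length(grid) < 1 || anyNA(grid), "`grid` must be non-empty")
  abort_if(!is_count(runs) || runs < 1, "`runs` must be a positive integer")
  grid <- sort(as.numeric(grid))
  seeds <- spawn_seeds(seed, 2L * runs)
  errors <- matrix(NA_real_, runs, length(grid))
  sparse <- matrix(NA_real_, runs, length(grid))
  for (r in seq_len(runs)) {
    weights <- sensory_weights(n_neurons, seed = seeds[[2L * r - 1L]])
    for (i in seq_along(grid)) {
      th <- threshold_spec(grid[[i]], n_neurons,
                           heterogeneity_sd = heterogeneity_sd,
                           seed = seeds[[2L * r - 1L]])
      coding <- coding_layer(weights, th, activation)
      fit <- train(geometry, coding, params, seed = seeds[[2L * r]])
      errors[r, i] <- fit$converged_error
      sparse[r, i] <- sparseness(coding, geometry)
    }
  }
  mean_error <- colMeans(errors)
  best <- which.min(mean_error)
  structure(list(grid = grid,
                 mean_error = mean_error,
                 sd_error = apply(errors, 2, stats::sd),
                 sparseness = colMeans(sparse),
                 errors = errors,
                 runs = as.integer(runs),
                 heterogeneity_sd = heterogeneity_sd,
                 opt_theta = grid[[best]],
                 opt_sparseness = colMeans(sparse)[[best]],
                 seed = as.integer(seed)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "sweep_result: %d thresholds x %d runs; optimal theta %.2f (sparseness %.3f)\n",
    length(x$grid), x$runs, x$opt_theta, x$opt_sparseness))
  invisible(x)
}

#' Eigenvalue spectrum of the activity covariance
#'
#' Principal component analysis of the population activity over task
#' conditions: conditions are the observations, neurons the variables,
#' and the covariance is centered over conditions.  The number of
#' meaningfully nonzero eigenvalues measures how decorrelated the code
#' is; it can never exceed the number of input conditions.
#'
#' @param patterns an `N` x `C` activity matrix from
#'   [activity_matrix()].
#' @param tol relative tolerance below which an eigenvalue counts as
#'   zero (`tol * largest`).
#' @return An object of class `spectrum_result` with `eigenvalues`
#'   (non-increasing), `contributions` (percent, summing to 100),
#'   `n_nonzero` and `degenerate` flag.
#' @export
pca_contributions <- function(patterns, tol = 1e-10) {
  abort_if(!is.matrix(patterns) || ncol(patterns) < 2,
           "`patterns` must be a matrix with at least 2 conditions")
  X <- t(patterns)                      # conditions x neurons
  X <- sweep(X, 2, colMeans(X))         # center over conditions
  C <- nrow(X)
  # eigenvalues of cov(X) via the C x C Gram matrix (N can be large)
  ev <- eigen(tcrossprod(X) / (C - 1), symmetric = TRUE, only.values = TRUE)
  lambda <- pmax(ev$values, 0)
  total <- sum(lambda)
  if (total <= 0) {
    return(structure(list(eigenvalues = lambda,
                          contributions = rep(NA_real_, length(lambda)),
                          n_nonzero = 0L, degenerate = TRUE),
                     class = "spectrum_result"))
  }
  structure(list(eigenvalues = lambda,
                 contributions = 100 * lambda / total,
                 n_nonzero = sum(lambda > tol * lambda[[1]]),
                 degenerate = FALSE),
            class = "spectrum_result")
}

#' Generalization error on novel targets
#'
#' Freezes the learned neuron-to-muscle map and measures the mean
#' squared movement error over `L` novel visual targets crossed with
#' every posture (`L = 500` and 3 postures give the standard 1500 test
#' movements).  Novel target angles are drawn uniformly on `[0, 2*pi)`
#' by default, or evenly spaced with `method = "even"`.
#'
#' @param W trained weight matrix (or a `train_result`).
#' @param coding the [coding_layer()] used in training.
#' @param geometry a [task_geometry()].
#' @param L number of novel targets (default 500).
#' @param seed RNG seed for the novel angles.
#' @param method `"random"` (default) or `"even"`.
#' @return Mean squared movement error (scalar).
#' @export
generalization_error <- function(W, coding, geometry = task_geometry(),
                                 L = 500L, seed = 1L,
                                 method = c("random", "even")) {
  method <- match.arg(method)
  if (inherits(W, "train_result")) W <- W$W
  abort_if(!is_count(L) || L < 1, "`L` must be a positive integer")
  angles <- if (method == "random") {
    with_seed(seed, stats::runif(L, 0, 2 * pi))
  } else {
    2 * pi * (seq_len(L) - 1) / L
  }
  V <- unit_vectors(angles)
  drive_v <- coding$weights$J_v %*% V                        # N x L
  drive_p <- coding$weights$J_p %*% geometry$postures$vectors
  proj <- geometry$muscles$projections
  total <- 0
  for (j in seq_len(geometry$postures$count)) {
    u <- drive_v + drive_p[, j] - coding$thresholds$values
    r <- apply_activation(u, coding$activation)
    nrm <- sqrt(colSums(r * r))
    nrm[nrm == 0] <- 1
    A <- sweep(r, 2, nrm, "/")
    M <- pmax(W %*% A, 0)                                    # N_M x L
    X <- proj[, , j] %*% M                                   # 2 x L
    total <- total + sum((V - X)^2)
  }
  total / (L * geometry$postures$count)
}

#' Tuning table of one neuron
#'
#' Activity of neuron `i` across every (target, posture) condition,
#' arranged targets x postures -- the simulated analogue of a direction
#' tuning curve measured in each forearm posture.
#'
#' @param neuron neuron index.
#' @param coding a [coding_layer()].
#' @param geometry a [task_geometry()].
#' @return A `K` x `n_postures` matrix of class `tuning_matrix` with
#'   target angles as rownames and posture labels as colnames.
#' @export
tuning_matrix <- function(neuron, coding, geometry = task_geometry()) {
  abort_if(!is_count(neuron) || neuron < 1 || neuron > coding$n_neurons,
           "`neuron` index out of range")
  A <- activity_matrix(coding, geometry)
  K <- geometry$targets$K
  tm <- matrix(A[neuron, ], K, geometry$postures$count,
               dimnames = list(signif(geometry$targets$angles, 4),
                               geometry$postures$labels))
  class(tm) <- c("tuning_matrix", class(tm))
  tm
}

# Best rank-1 nonnegative approximation f %o% g of a nonnegative table,
# by alternating least squares.
rank1_nonneg <- function(tm, max_iter = 100L, tol = 1e-10) {
  f <- pmax(rowMeans(tm), 0)
  if (all(f == 0)) f <- rep(1, nrow(tm))
  g <- rep(0, ncol(tm))
  last <- Inf
  for (iter in seq_len(max_iter)) {
    g <- pmax(as.vector(crossprod(tm, f)) / sum(f * f), 0)
    if (all(g == 0)) break
    f <- pmax(as.vector(tm %*% g) / sum(g * g), 0)
    if (all(f == 0)) break
    rss <- sum((tm - tcrossprod(f, g))^2)
    if (abs(last - rss) < tol) break
    last <- rss
  }
  tcrossprod(f, g)
}

#' Classify tuning modulation as additive or multiplicative
#'
#' Fits two models of how posture modulates a neuron's target tuning:
#' additive, `A[k, kp] = f(k) + g(kp)` (two-way main effects, least
#' squares), and multiplicative, `A[k, kp] = f(k) * g(kp)` (best
#' nonnegative rank-1 approximation, alternating least squares).  The
#' models have equal complexity, so the winner is simply the one with
#' the smaller residual sum of squares -- but the call is only definite
#' when the winner's residual is at least `ratio` times smaller than
#' the loser's; otherwise the neuron is `"ambiguous"`.  (A margin on
#' the raw R-squared difference fails here: both models fit well-tuned
#' neurons nearly perfectly, so even a table that is *exactly* additive
#' would land within any fixed R-squared margin of the rank-1 fit.)
#' A table with (numerically) no variance is `"flat"`.
#'
#' @param tm a [tuning_matrix()] (any numeric targets x postures
#'   matrix works).
#' @param ratio required residual-sum-of-squares advantage of the
#'   winning model for a definite call (default 2).
#' @param flat_tol activity scale below which the neuron counts as flat.
#' @return An object of class `modulation_fit` with `r2_additive`,
#'   `r2_multiplicative` and `classification` in
#'   `c("additive", "multiplicative", "flat", "ambiguous")`.
#' @export
modulation_fit <- function(tm, ratio = 2, flat_tol = 1e-6) {
  abort_if(!is.matrix(tm) || !is.numeric(unclass(tm)),
           "`tm` must be a numeric matrix")
  abort_if(!is_scalar(ratio) || ratio < 1, "`ratio` must be >= 1")
  tm <- unclass(tm)
  ss_tot <- sum((tm - mean(tm))^2)
  if (max(abs(tm)) <= flat_tol || ss_tot <= flat_tol^2) {
    return(structure(list(r2_additive = NA_real_,
                          r2_multiplicative = NA_real_,
                          classification = "flat"),
                     class = "modulation_fit"))
  }
  add_hat <- outer(rowMeans(tm), colMeans(tm), "+") - mean(tm)
  ss_add <- sum((tm - add_hat)^2)
  ss_mul <- sum((tm - rank1_nonneg(tm))^2)
  classification <- if (ss_mul * ratio <= ss_add) {
    "multiplicative"
  } else if (ss_add * ratio <= ss_mul) {
    "additive"
  } else {
    "ambiguous"
  }
  structure(list(r2_additive = 1 - ss_add / ss_tot,
                 r2_multiplicative = 1 - ss_mul / ss_tot,
                 classification = classification),
            class = "modulation_fit")
}

#' Census of modulation classes over a population
#'
#' Applies [modulation_fit()] to every neuron that is active somewhere
#' in the task and tabulates the classifications.
#'
#' @param coding a [coding_layer()].
#' @param geometry a [task_geometry()].
#' @param ratio,flat_tol passed to [modulation_fit()].
#' @return A named integer vector with counts for `additive`,
#'   `multiplicative`, `ambiguous` and `flat`.
#' @export
modulation_census <- function(coding, geometry = task_geometry(),
                              ratio = 2, flat_tol = 1e-6) {
  A <- activity_matrix(coding, geometry)
  K <- geometry$targets$K
  n_post <- geometry$postures$count
  classes <- vapply(seq_len(nrow(A)), function(i) {
    modulation_fit(matrix(A[i, ], K, n_post), ratio, flat_tol)$classification
  }, character(1))
  counts <- table(factor(classes, levels = c("additive", "multiplicative",
                                             "ambiguous", "flat")))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
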