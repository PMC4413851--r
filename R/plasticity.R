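#' Neuron-to-muscle connection matrix
#'
#' The adaptable readout `W` maps the `N`-dimensional population
#' activity to `N_M` muscle drives.  The main threshold-linear model
#' starts from `W = 0`; the comparison networks start from small
#' Gaussian weights (sd `1/sqrt(N)` by default, keeping the initial
#' drive O(1)).
#'
#' @param n_muscles number of muscles.
#' @param n_neurons number of neurons.
#' @param init `"zero"` (default) or `"gaussian"`.
#' @param sd standard deviation for Gaussian init; defaults to
#'   `1/sqrt(n_neurons)`.
#' @param seed RNG seed for Gaussian init.
#' @return An object of class `muscle_map` with matrix `W`.
#' @export
muscle_map <- function(n_muscles, n_neurons, init = c("zero", "gaussian"),
                       sd = NULL, seed = 1L) {
  init <- match.arg(init)
  abort_if(!is_count(n_muscles) || n_muscles < 1,
           "`n_muscles` must be a positive integer")
  abort_if(!is_count(n_neurons) || n_neurons < 1,
           "`n_neurons` must be a positive integer")
  W <- if (init == "zero") {
    matrix(0, n_muscles, n_neurons)
  } else {
    if (is.null(sd)) sd <- 1 / sqrt(n_neurons)
    with_seed(seed, matrix(stats::rnorm(n_muscles * n_neurons, 0, sd),
                           n_muscles, n_neurons))
  }
  structure(list(W = W, n_muscles = as.integer(n_muscles),
                 n_neurons = as.integer(n_neurons), init = init),
            class = "muscle_map")
}

#' Learning parameters
#'
#' @param eta learning rate (default 0.4).
#' @param lambda weight of the squared-muscle-activity cost term
#'   (default 0; it does not influence the converged movement error).
#' @param n_trials number of training trials (default 20000, by which
#'   the movement error has converged in the standard configuration;
#'   the full-length reference protocol uses 1e6).
#' @param window fractional convergence window `c(start, end)` over
#'   which the converged error is averaged; the default `c(0.9, 1)` is
#'   the final 10 percent of trials.
#' @param adaptable which weight sets learning may change: `"W"`
#'   (default), `"J"`, or `c("W", "J")`.  Adapting `J` requires a
#'   saturating activation (comparison networks).
#' @return An object of class `learning_params`.
#' @export
learning_params <- function(eta = 0.4, lambda = 0, n_trials = 20000L,
                            window = c(0.9, 1), adaptable = "W") {
  abort_if(!is_scalar(eta) || eta < 0, "`eta` must be a nonnegative scalar")
  abort_if(!is_scalar(lambda) || lambda < 0,
           "`lambda` must be a nonnegative scalar")
  abort_if(!is_count(n_trials) || n_trials < 1,
           "`n_trials` must be a positive integer")
  abort_if(length(window) != 2L || window[1] < 0 || window[2] > 1 ||
             window[1] >= window[2], "`window` must be fractions 0 <= a < b <= 1")
  abort_if(!all(adaptable %in% c("W", "J")) || length(adaptable) < 1,
           "`adaptable` must be a subset of c(\"W\", \"J\")")
  structure(list(eta = eta, lambda = lambda, n_trials = as.integer(n_trials),
                 window = window, adaptable = unique(adaptable)),
            class = "learning_params")
}

#' Rectified muscle activity
#'
#' Muscle activity is the rectified linear readout `M = pmax(W %*% A, 0)`.
#'
#' @param W `N_M` x `N` weight matrix (or a [muscle_map()]).
#' @param A activity vector of length `N` (or an `activity` object).
#' @return A list with `M` (muscle activities), `drive` (`W %*% A`
#'   before rectification) and logical `active` (`M > 0`).
#' @export
muscle_activity <- function(W, A) {
  if (inherits(W, "muscle_map")) W <- W$W
  if (inherits(A, "activity")) A <- A$values
  abort_if(!is.matrix(W) || ncol(W) != length(A),
           "`W` columns must match the length of `A`")
  drive <- as.vector(W %*% A)
  M <- pmax(drive, 0)
  list(M = M, drive = drive, active = M > 0)
}

#' Zero out projection columns of inactive muscles
#'
#' The learning rule only propagates error through muscles on the
#' active side of the rectification; their projection columns survive,
#' the rest are zeroed.
#'
#' @param P 2 x `N_M` projection matrix.
#' @param active logical mask of length `N_M`.
#' @return A copy of `P` with inactive columns set to zero.
#' @export
masked_projection <- function(P, active) {
  abort_if(!is.matrix(P) || length(active) != ncol(P),
           "`active` must have one entry per column of `P`")
  P[, !active] <- 0
  P
}

#' One gradient step on the neuron-to-muscle weights
#'
#' Descends the per-trial cost
#' `0.5 * ||v - P %*% pmax(W %*% A, 0)||^2 + 0.5 * lambda * sum(M^2)`:
#' `W' = W + eta * (t(P_plus) %*% e - lambda * M) %*% t(A)`, where
#' `P_plus` is the masked projection.  A silent trial (`A = 0`) leaves
#' `W` unchanged.
#'
#' @param W weight matrix.
#' @param e movement error vector (length 2).
#' @param A activity vector (or `activity` object).
#' @param P_plus masked projection matrix.
#' @param eta learning rate.
#' @param lambda muscle-cost weight.
#' @param M muscle activity vector; required when `lambda > 0`.
#' @return The updated weight matrix.
#' @export
update_W <- function(W, e, A, P_plus, eta = 0.4, lambda = 0, M = NULL) {
  if (inherits(A, "activity")) A <- A$values
  abort_if(!is.matrix(W), "`W` must be a matrix")
  abort_if(length(e) != 2L, "`e` must be a 2-vector")
  abort_if(ncol(W) != length(A), "`A` must match the columns of `W`")
  abort_if(!is.matrix(P_plus) || ncol(P_plus) != nrow(W),
           "`P_plus` must be 2 x n_muscles")
  if (all(A == 0)) return(W)
  g <- as.vector(crossprod(P_plus, e))
  if (lambda > 0) {
    abort_if(is.null(M), "`M` is required when `lambda` > 0")
    g <- g - lambda * M
  }
  W + eta * tcrossprod(g, A)
}

#' Mean squared error over the convergence window
#'
#' @param result a `train_result` (or a numeric error trace).
#' @param window fractional window `c(start, end)`; defaults to the
#'   window stored in the result (last 10 percent of trials).
#' @return The arithmetic mean of the squared movement error over the
#'   window.
#' @export
converged_error <- function(result, window = NULL) {
  trace <- if (inherits(result, "train_result")) result$error else result
  abort_if(!is.numeric(trace) || length(trace) < 1,
           "`result` must contain a numeric error trace")
  if (is.null(window)) {
    window <- if (inherits(result, "train_result")) result$window else c(0.9, 1)
  }
  n <- length(trace)
  lo <- floor(window[1] * n) + 1L
  hi <- ceiling(window[2] * n)
  abort_if(lo > hi || lo < 1 || hi > n, "empty or out-of-range window")
  mean(trace[lo:hi])
}

#' Train a network on the sensorimotor transformation task
#'
#' Runs the per-trial simulation loop: sample a (target, posture) pair,
#' compute the normalized population activity, the rectified muscle
#' activity and the executed movement, observe the movement error, and
#' take one gradient step on the adaptable weights.  With fixed sensory
#' weights (`adaptable = "W"`) the activity takes only `C` distinct
#' values, and the trainer runs in an exactly equivalent factored
#' `C`-dimensional form (compiled); `method = "direct"` forces the
#' plain `N`-dimensional reference loop used for validation.
#'
#' @param geometry a [task_geometry()].
#' @param coding a [coding_layer()].
#' @param params a [learning_params()].
#' @param W0 optional initial [muscle_map()]; defaults to zeros for
#'   `adaptable = "W"` and Gaussian for the comparison networks.
#' @param seed RNG seed for the trial schedule.
#' @param method `"auto"` (default), `"factored"` or `"direct"`.
#' @return An object of class `train_result` with the per-trial squared
#'   error trace, final `W`, final `coding` (with adapted `J` when
#'   applicable), the convergence `window`, `converged_error`, `seed`
#'   and `method`.
#' @export
train <- function(geometry, coding, params = learning_params(), W0 = NULL,
                  seed = 1L, method = c("auto", "factored", "direct")) {
  method <- match.arg(method)
  abort_if(!inherits(geometry, "task_geometry"),
           "`geometry` must be a task_geometry")
  abort_if(!inherits(coding, "coding_layer"),
           "`coding` must be a coding_layer")
  abort_if(!inherits(params, "learning_params"),
           "`params` must be a learning_params")

  adapt_J <- "J" %in% params$adaptable
  if (adapt_J) {
    abort_if(method == "factored",
             "factored training requires fixed sensory weights")
    abort_if(!coding$activation$kind %in% c("tanh_rectified", "tanh_positive"),
             "unsupported configuration: adapting J requires a tanh activation")
    return(train_adaptive_J(geometry, coding, params, W0, seed))
  }
  if (method == "auto") method <- "factored"

  n_m <- geometry$muscles$n_muscles
  if (is.null(W0)) W0 <- muscle_map(n_m, coding$n_neurons)
  if (inherits(W0, "muscle_map")) W0 <- W0$W
  abort_if(!all(dim(W0) == c(n_m, coding$n_neurons)),
           "`W0` has wrong dimensions")

  schedule <- trial_schedule(params$n_trials, geometry$targets$K,
                             geometry$postures$count, seed)
  Act <- activity_matrix(coding, geometry)
  silent <- attr(Act, "silent")

  if (method == "factored") {
    abort_if(any(W0 != 0),
             "factored training assumes the zero initial W of the main model")
    fit <- .train_factored_cpp(crossprod(Act), silent,
                               as.vector(geometry$muscles$projections),
                               n_m, geometry$postures$count,
                               geometry$targets$vectors,
                               schedule$k, schedule$kp,
                               params$eta, params$lambda)
    W <- fit$G %*% t(Act)
    err <- fit$error
  } else {
    fit <- train_direct_r(Act, silent, geometry, schedule, params, W0)
    W <- fit$W
    err <- fit$error
  }

  res <- structure(list(error = err, W = W, coding = coding,
                        window = params$window, seed = as.integer(seed),
                        params = params, method = method),
                   class = "train_result")
  res$converged_error <- converged_error(res)
  res
}

# Reference N-dimensional training loop (R, used for validation and for
# nonzero W0).  Muscles exactly at the rectification kink (drive == 0)
# count as active so that learning can start from W0 = 0.
train_direct_r <- function(Act, silent, geometry, schedule, params, W0) {
  W <- W0
  K <- geometry$targets$K
  proj <- geometry$muscles$projections
  V <- geometry$targets$vectors
  err <- numeric(params$n_trials)
  for (t in seq_len(params$n_trials)) {
    k <- schedule$k[[t]]
    kp <- schedule$kp[[t]]
    v <- V[, k]
    cc <- condition_index(k, kp, K)
    if (silent[[cc]]) {
      err[[t]] <- sum(v * v)
      next
    }
    A <- Act[, cc]
    drive <- as.vector(W %*% A)
    M <- pmax(drive, 0)
    e <- v - as.vector(proj[, , kp] %*% M)
    err[[t]] <- sum(e * e)
    P_plus <- masked_projection(proj[, , kp], drive >= 0)
    W <- update_W(W, e, A, P_plus, params$eta, params$lambda, M)
  }
  list(W = W, error = err)
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf(
    "train_result: %d trials (%s), converged error %.3e over window [%g, %g]\n",
    length(x$error), x$method, x$converged_error,
    x$window[1], x$window[2]))
  invisible(x)
}
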