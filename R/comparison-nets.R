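# Comparison networks: saturating (tanh-family) activation with
# adaptable sensory weights J, used to ask whether nonlinearity alone
# (without sparse coding) suffices to learn the task.

# Full forward pass plus analytic gradients of the per-trial cost
#   C = 0.5 * ||v - P %*% pmax(W %*% A, 0)||^2 + 0.5 * lambda * sum(M^2)
# with respect to W, J_v and J_p, differentiating through the
# activation and the unit-norm (fixed metabolic cost) normalization.
# Used by the adaptive-J trainer and by the finite-difference oracle
# tests.
cost_gradients <- function(coding, W, v, p, P, lambda = 0) {
  J_v <- coding$weights$J_v
  J_p <- coding$weights$J_p
  theta <- coding$thresholds$values
  beta <- coding$activation$beta
  u <- as.vector(J_v %*% v + J_p %*% p) - theta
  r <- apply_activation(u, coding$activation)
  nrm2 <- sum(r * r)
  if (nrm2 == 0) {
    return(list(silent = TRUE, cost = sum(v * v), e = v,
                grad_W = 0 * W, grad_Jv = 0 * J_v, grad_Jp = 0 * J_p))
  }
  nrm <- sqrt(nrm2)
  A <- r / nrm
  drive <- as.vector(W %*% A)
  M <- pmax(drive, 0)
  x <- as.vector(P %*% M)
  e <- v - x
  cost <- 0.5 * sum(e * e) + 0.5 * lambda * sum(M * M)

  mask <- drive >= 0
  dC_dM <- as.vector(crossprod(P, -e)) + lambda * M
  dC_ddrive <- ifelse(mask, dC_dM, 0)
  grad_W <- tcrossprod(dC_ddrive, A)

  dC_dA <- as.vector(crossprod(W, dC_ddrive))
  dC_dr <- (dC_dA - A * sum(A * dC_dA)) / nrm
  drdu <- switch(coding$activation$kind,
    threshold_linear = as.numeric(u > 0),
    tanh_rectified   = ifelse(tanh(beta * u) > 0,
                              beta * (1 - tanh(beta * u)^2), 0),
    sigmoid          = {
      s <- stats::plogis(beta * u)
      ifelse(s > 0.5, beta * s * (1 - s), 0)
    },
    tanh_positive    = beta / 2 * (1 - tanh(beta * u)^2))
  dC_du <- dC_dr * drdu
  list(silent = FALSE, cost = cost, e = e, A = A, M = M,
       grad_W = grad_W,
       grad_Jv = tcrossprod(dC_du, v),
       grad_Jp = tcrossprod(dC_du, p))
}

#' One gradient step on the sensory weights
#'
#' For the comparison networks the sensory weights `J_v`, `J_p` descend
#' the same per-trial cost as `W`, with the chain rule taken through
#' the saturating activation and the unit-norm normalization.  Requires
#' a tanh-family activation; the main threshold-linear model keeps `J`
#' fixed.
#'
#' @param coding a [coding_layer()] with `tanh_rectified` or
#'   `tanh_positive` activation.
#' @param W current neuron-to-muscle weights.
#' @param v,p trial input unit vectors.
#' @param P the trial posture's 2 x `N_M` projection matrix.
#' @param eta learning rate.
#' @param lambda muscle-cost weight.
#' @return The `coding` object with updated `J_v` and `J_p`; unchanged
#'   on a silent trial or when the movement error is zero.
#' @export
update_J <- function(coding, W, v, p, P, eta = 0.4, lambda = 0) {
  abort_if(!inherits(coding, "coding_layer"),
           "`coding` must be a coding_layer")
  abort_if(!coding$activation$kind %in% c("tanh_rectified", "tanh_positive"),
           "unsupported configuration: adapting J requires a tanh activation")
  if (inherits(W, "muscle_map")) W <- W$W
  g <- cost_gradients(coding, W, v, p, P, lambda)
  if (g$silent) return(coding)
  coding$weights$J_v <- coding$weights$J_v - eta * g$grad_Jv
  coding$weights$J_p <- coding$weights$J_p - eta * g$grad_Jp
  coding
}

# Trial loop for networks whose J (and optionally W) adapt.  Activities
# must be recomputed every trial because J changes.
train_adaptive_J <- function(geometry, coding, params, W0, seed) {
  n_m <- geometry$muscles$n_muscles
  if (is.null(W0)) {
    W0 <- muscle_map(n_m, coding$n_neurons, init = "gaussian",
                     seed = seed + 1L)
  }
  if (inherits(W0, "muscle_map")) W0 <- W0$W
  abort_if(!all(dim(W0) == c(n_m, coding$n_neurons)),
           "`W0` has wrong dimensions")
  adapt_W <- "W" %in% params$adaptable
  schedule <- trial_schedule(params$n_trials, geometry$targets$K,
                             geometry$postures$count, seed)
  V <- geometry$targets$vectors
  Pv <- geometry$postures$vectors
  proj <- geometry$muscles$projections
  W <- W0
  err <- numeric(params$n_trials)
  for (t in seq_len(params$n_trials)) {
    k <- schedule$k[[t]]
    kp <- schedule$kp[[t]]
    v <- V[, k]
    g <- cost_gradients(coding, W, v, Pv[, kp], proj[, , kp], params$lambda)
    err[[t]] <- sum(g$e * g$e)
    if (g$silent) next
    coding$weights$J_v <- coding$weights$J_v - params$eta * g$grad_Jv
    coding$weights$J_p <- coding$weights$J_p - params$eta * g$grad_Jp
    if (adapt_W) W <- W - params$eta * g$grad_W
  }
  res <- structure(list(error = err, W = W, coding = coding,
                        window = params$window, seed = as.integer(seed),
                        params = params, method = "adaptive_J"),
                   class = "train_result")
  res$converged_error <- converged_error(res)
  res
}
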