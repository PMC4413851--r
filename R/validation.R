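# Independent oracles and tiny deterministic fixtures backing the test
# suite.

#' Central finite-difference gradient
#'
#' Numerical gradient oracle used to validate every analytic gradient
#' in the package: each entry of `x` is perturbed by `+h` and `-h` and
#' the centered difference of `f` taken.
#'
#' @param f scalar-valued function of a numeric vector/matrix.
#' @param x point at which to differentiate (vector or matrix).
#' @param h step size (default 1e-6).
#' @return Numeric gradient with the shape of `x`.
#' @export
finite_difference_gradient <- function(f, x, h = 1e-6) {
  abort_if(!is.numeric(x), "`x` must be numeric")
  abort_if(!is_scalar(h) || h <= 0, "`h` must be a positive scalar")
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    fp <- f(xp); fm <- f(xm)
    abort_if(!is.finite(fp) || !is.finite(fm),
             "oracle failure: non-finite cost at perturbed parameters")
    g[i] <- (fp - fm) / (2 * h)
  }
  g
}

#' Deterministic miniature network fixtures
#'
#' Frozen tiny instances for tests: `"tiny-sparse"` (N = 6, K = 2, one
#' posture, threshold searched so that exactly half the neurons are
#' never active, sparseness 0.5) and `"tiny-dense"` (same weights,
#' threshold -10, every neuron active everywhere, sparseness 0).
#'
#' @param name fixture name.
#' @return A list with `geometry`, `coding`, `params` and `seed`.
#' @export
make_fixture <- function(name = c("tiny-sparse", "tiny-dense")) {
  abort_if(!is.character(name) || length(name) != 1L,
           "`name` must be a single string")
  abort_if(!name %in% c("tiny-sparse", "tiny-dense"),
           sprintf("unknown fixture name '%s'", name))
  seed <- 2024L
  geometry <- task_geometry(
    targets = target_set(2L),
    postures = posture_set(0, labels = "midrange"),
    muscles = muscle_geometry(3L, posture_rotations = 0))
  weights <- sensory_weights(6L, seed = seed)
  theta <- if (name == "tiny-dense") {
    -10
  } else {
    # smallest grid value silencing exactly 3 of the 6 neurons over all
    # conditions
    pre <- weights$J_v %*% geometry$targets$vectors +
      as.vector(weights$J_p %*% geometry$postures$vectors[, 1])
    sort(apply(pre, 1, max))[3]
  }
  coding <- coding_layer(weights, threshold_spec(theta, 6L))
  list(name = name, geometry = geometry, coding = coding,
       params = learning_params(n_trials = 2000L), seed = seed)
}
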