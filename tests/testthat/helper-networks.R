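# Small network builders shared across test files.

uv <- function(angles) rbind(cos(angles), sin(angles))

small_geometry <- function(K = 4L, n_post = 2L, n_muscles = 3L) {
  task_geometry(
    targets = target_set(K),
    postures = posture_set(seq(0, pi / 4, length.out = n_post),
                           labels = paste0("p", seq_len(n_post))),
    muscles = muscle_geometry(n_muscles,
                              posture_rotations = seq(0, pi / 4,
                                                      length.out = n_post)))
}

small_coding <- function(n_neurons = 8L, theta = 0.5, seed = 3L,
                         activation = activation_spec()) {
  coding_layer(sensory_weights(n_neurons, seed = seed),
               threshold_spec(theta, n_neurons), activation)
}

# Coding layer with explicitly chosen weight matrices (the constructors
# are plain lists, so tests may overwrite the sampled values).
manual_coding <- function(J_v, J_p, theta, activation = activation_spec()) {
  n <- nrow(J_v)
  w <- sensory_weights(n, seed = 1L)
  w$J_v <- J_v
  w$J_p <- J_p
  coding_layer(w, threshold_spec(theta, n), activation)
}

# Random kink-free instance of the muscle stage: activity, weights and
# projection with every muscle drive bounded away from the
# rectification kink.
random_muscle_instance <- function(n_neurons = 6L, n_muscles = 3L,
                                   kink_tol = 1e-3, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    A <- abs(stats::rnorm(n_neurons))
    A <- A / sqrt(sum(A^2))
    W <- matrix(stats::rnorm(n_muscles * n_neurons), n_muscles, n_neurons)
    P <- uv(stats::runif(n_muscles, 0, 2 * pi))
    v <- as.vector(uv(stats::runif(1, 0, 2 * pi)))
    drive <- as.vector(W %*% A)
    if (all(abs(drive) > kink_tol)) {
      return(list(A = A, W = W, P = P, v = v, drive = drive))
    }
  }
  stop("could not generate a kink-free instance")
}
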