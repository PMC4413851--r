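#' Visual target set on the unit circle
#'
#' Builds the `K` reach targets of the visually guided wrist-movement
#' task.  Target `k` lies at angle `start_angle + 2*pi*(k-1)/K` on the
#' unit circle; the cursor must be driven onto it by muscle activity.
#'
#' @param K number of targets (default 8).
#' @param start_angle angle of the first target in radians (default 0).
#' @return An object of class `target_set` with elements `K`, `angles`
#'   (length-`K` numeric) and `vectors` (a 2 x `K` matrix whose columns
#'   are unit vectors).
#' @examples
#' tg <- target_set(8)
#' tg$vectors[, 1]  # c(1, 0)
#' @export
target_set <- function(K = 8L, start_angle = 0) {
  abort_if(!is_count(K) || K < 1, "`K` must be a positive integer")
  abort_if(!is_scalar(start_angle), "`start_angle` must be a finite scalar")
  angles <- start_angle + 2 * pi * (seq_len(K) - 1) / K
  structure(list(K = as.integer(K), angles = angles,
                 vectors = unit_vectors(angles)),
            class = "target_set")
}

#' Forearm posture set
#'
#' Proprioceptive posture inputs are unit vectors on the circle, one per
#' forearm posture.  The defaults place pronation, midrange and
#' supination at `-pi/4`, `0` and `pi/4`; the simulation results do not
#' depend on the specific values as long as the postures are distinct.
#'
#' @param angles posture angles in radians.
#' @param labels optional character labels, recycled defaults cover the
#'   three-posture case.
#' @return An object of class `posture_set` with `count`, `labels`,
#'   `angles` and a 2 x count matrix `vectors` of unit columns.
#' @export
posture_set <- function(angles = c(-pi / 4, 0, pi / 4), labels = NULL) {
  abort_if(length(angles) < 1 || !is.numeric(angles) || anyNA(angles),
           "`angles` must be a non-empty numeric vector")
  if (is.null(labels)) {
    labels <- if (length(angles) == 3L) {
      c("pronation", "midrange", "supination")
    } else {
      paste0("posture", seq_along(angles))
    }
  }
  abort_if(length(labels) != length(angles),
           "`labels` must match `angles` in length")
  structure(list(count = length(angles), labels = labels,
                 angles = as.numeric(angles),
                 vectors = unit_vectors(angles)),
            class = "posture_set")
}

#' Posture-dependent muscle pulling geometry
#'
#' Each muscle pulls the cursor along a posture-dependent direction
#' `phi[i, k']`; the projection matrix `P_k'` mapping muscle activity to
#' 2-D movement has columns `(cos phi[i,k'], sin phi[i,k'])`.  Pulling
#' directions are modelled as fixed base angles rigidly rotated with the
#' forearm: `phi[i, k'] = base_angles[i] + posture_rotations[k']`.
#'
#' @param n_muscles number of muscles (default 5).
#' @param base_angles pulling directions in the reference posture; the
#'   default spreads them evenly over the circle.
#' @param posture_rotations one rigid rotation per posture (radians);
#'   defaults to the posture angles `(-pi/4, 0, pi/4)`.
#' @return An object of class `muscle_geometry` with `n_muscles`,
#'   `pulling_angles` (`n_muscles` x postures) and `projections`
#'   (2 x `n_muscles` x postures array).
#' @export
muscle_geometry <- function(n_muscles = 5L,
                            base_angles = NULL,
                            posture_rotations = c(-pi / 4, 0, pi / 4)) {
  abort_if(!is_count(n_muscles) || n_muscles < 1,
           "`n_muscles` must be a positive integer")
  if (is.null(base_angles)) {
    base_angles <- 2 * pi * (seq_len(n_muscles) - 1) / n_muscles
  }
  abort_if(length(base_angles) != n_muscles,
           "`base_angles` must have one entry per muscle")
  abort_if(length(posture_rotations) < 1 || anyNA(posture_rotations),
           "`posture_rotations` must be a non-empty numeric vector")
  n_post <- length(posture_rotations)
  phi <- outer(base_angles, posture_rotations, "+")
  proj <- array(NA_real_, dim = c(2L, n_muscles, n_post))
  for (j in seq_len(n_post)) proj[, , j] <- unit_vectors(phi[, j])
  structure(list(n_muscles = as.integer(n_muscles),
                 base_angles = as.numeric(base_angles),
                 posture_rotations = as.numeric(posture_rotations),
                 pulling_angles = phi, projections = proj),
            class = "muscle_geometry")
}

#' Bundle task geometry
#'
#' Combines targets, postures and muscles into one task description used
#' by [train()], [activity_matrix()] and the analysis functions.
#'
#' @param targets a [target_set()].
#' @param postures a [posture_set()].
#' @param muscles a [muscle_geometry()]; must have one posture rotation
#'   per posture.
#' @return An object of class `task_geometry`.
#' @export
task_geometry <- function(targets = target_set(),
                          postures = posture_set(),
                          muscles = muscle_geometry()) {
  abort_if(!inherits(targets, "target_set"), "`targets` must be a target_set")
  abort_if(!inherits(postures, "posture_set"),
           "`postures` must be a posture_set")
  abort_if(!inherits(muscles, "muscle_geometry"),
           "`muscles` must be a muscle_geometry")
  abort_if(length(muscles$posture_rotations) != postures$count,
           "`muscles` must define one posture rotation per posture")
  structure(list(targets = targets, postures = postures, muscles = muscles,
                 n_conditions = targets$K * postures$count),
            class = "task_geometry")
}

#' @export
print.task_geometry <- function(x, ...) {
  cat(sprintf(
    "task_geometry: %d targets x %d postures (%d conditions), %d muscles\n",
    x$targets$K, x$postures$count, x$n_conditions, x$muscles$n_muscles))
  invisible(x)
}

# Linear index of condition (target k, posture kp) into the K * postures
# condition list; posture-major blocks of K targets.
condition_index <- function(k, kp, K) (kp - 1L) * K + k

condition_labels <- function(geometry) {
  K <- geometry$targets$K
  n_post <- geometry$postures$count
  as.vector(outer(seq_len(K), seq_len(n_post),
                  function(k, kp) paste0(k, "_", kp)))
}

#' Random trial schedule
#'
#' Draws, for each of `n_trials` trials, a target index `k(t)` and a
#' posture index `kp(t)`, each independent and uniform, reproducibly
#' from `seed`.
#'
#' @param n_trials number of trials.
#' @param K number of targets.
#' @param n_postures number of postures.
#' @param seed RNG seed.
#' @return An object of class `trial_schedule` with integer vectors `k`
#'   and `kp` of length `n_trials`.
#' @export
trial_schedule <- function(n_trials, K = 8L, n_postures = 3L, seed = 1L) {
  abort_if(!is_count(n_trials) || n_trials < 1,
           "`n_trials` must be a positive integer")
  abort_if(!is_count(K) || K < 1, "`K` must be a positive integer")
  abort_if(!is_count(n_postures) || n_postures < 1,
           "`n_postures` must be a positive integer")
  draws <- with_seed(seed, list(
    k = sample.int(K, n_trials, replace = TRUE),
    kp = sample.int(n_postures, n_trials, replace = TRUE)))
  structure(list(n_trials = as.integer(n_trials), K = as.integer(K),
                 n_postures = as.integer(n_postures), seed = as.integer(seed),
                 k = draws$k, kp = draws$kp),
            class = "trial_schedule")
}

#' Look up one trial of a schedule
#'
#' @param schedule a [trial_schedule()].
#' @param t trial index in `1..n_trials`.
#' @return A list with integer elements `k` (target) and `kp` (posture).
#' @export
sample_trial <- function(schedule, t) {
  abort_if(!inherits(schedule, "trial_schedule"),
           "`schedule` must be a trial_schedule")
  abort_if(!is_count(t) || t < 1 || t > schedule$n_trials,
           "trial index `t` out of range")
  list(k = schedule$k[[t]], kp = schedule$kp[[t]])
}

#' Execute a movement and measure its error
#'
#' The executed movement is `x = P %*% M` and the movement error is
#' `e = v - x`, where `P` is the posture's 2 x `N_M` projection matrix,
#' `M` the muscle activity vector and `v` the target.
#'
#' @param P 2 x `N_M` projection matrix.
#' @param M muscle activity vector of length `N_M`.
#' @param v target unit vector (length 2).
#' @return A list with `x` (movement) and `e` (error vector).
#' @export
execute_movement <- function(P, M, v) {
  abort_if(!is.matrix(P) || nrow(P) != 2L, "`P` must be a 2 x N_M matrix")
  abort_if(length(M) != ncol(P), "`M` must match the number of muscles")
  abort_if(length(v) != 2L, "`v` must be a 2-vector")
  x <- as.vector(P %*% M)
  list(x = x, e = v - x)
}
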