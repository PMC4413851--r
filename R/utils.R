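#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

abort_if <- function(cond, ..., call. = FALSE) {
  if (cond) stop(..., call. = call.)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards so simulations compose
# without clobbering each other.
with_seed <- function(seed, expr) {
  abort_if(!is_count(seed), "`seed` must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds spawned from one master seed; kept below
# 2^31 so they remain valid R integers.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

unit_vectors <- function(angles) {
  rbind(cos(angles), sin(angles))
}

check_unit <- function(v, name, tol = 1e-8) {
  abort_if(!is.numeric(v) || length(v) != 2L,
           sprintf("`%s` must be a numeric 2-vector", name))
  abort_if(abs(sum(v^2) - 1) > tol,
           sprintf("`%s` must have unit Euclidean norm", name))
  invisible(TRUE)
}
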