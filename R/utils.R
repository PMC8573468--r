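# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps generator calls free of global
# RNG side effects.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(expr)
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", field, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_number <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 field, format(min), format(max)), call. = FALSE)
  }
  as.numeric(x)
}

# Leading eigenpair of a symmetric operator given as a matvec closure, by
# shifted power iteration with a deterministic start vector. `shift` must
# dominate the spectral radius so the iteration converges to the largest
# algebraic eigenvalue.
power_leading <- function(matvec, n, shift, tol = 1e-10, max_iter = 1e5) {
  x <- 1 + 1e-6 * seq_len(n)  # deterministic, breaks symmetry
  x <- x / sqrt(sum(x^2))
  lambda <- 0
  for (i in seq_len(max_iter)) {
    y <- matvec(x) + shift * x
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(list(value = -shift, vector = x, iterations = i))
    y <- y / ny
    if (max(abs(y - x)) < tol) {
      x <- y
      break
    }
    x <- y
  }
  lambda <- sum(x * matvec(x))
  list(value = lambda, vector = x, iterations = i)
}
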