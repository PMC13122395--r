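# Internal helpers shared across modules.

# Classed error so callers can distinguish schema/validation/positivity failures.
stop_sdr <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "sdrshift_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  Keeps estimator/generator seeding local.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a master seed; stays below 2^31 - 1.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647L)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weighted mean with weights normalised to mean 1; returns list(point, if_values).
weighted_if_mean <- function(d, w = NULL) {
  n <- length(d)
  if (is.null(w)) w <- rep(1, n)
  w <- w / mean(w)
  point <- mean(w * d)
  iff <- w * (d - point) + point
  list(point = point, if_values = iff, se = stats::sd(iff) / sqrt(n))
}
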