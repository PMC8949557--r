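# Internal helpers shared across modules.

# Signal a classed error so callers can distinguish domain failures
# (e.g. unreachable moisture, cannot-actuate) from programming errors.
stop_eatdry <- function(subclass, message, call = sys.call(-1), ...) {
  cond <- structure(
    class = c(subclass, "eatdry_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run code with a private RNG stream: seeds, then restores the caller's
# .Random.seed so simulations do not perturb user-level randomness.
with_local_seed <- function(seed, code) {
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
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

# Derive a reproducible child seed below 2^31 from a base seed and an index.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
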