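# Classed conditions used across the package. Every user-facing error is one
# of these subclasses so callers (and the CLI) can distinguish bad arguments
# from numerical failures.

kld_stop <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "kld_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_invalid_parameter <- function(message) {
  kld_stop(message, "kld_invalid_parameter")
}

stop_invalid_input <- function(message) {
  kld_stop(message, "kld_invalid_input")
}

stop_not_positive_definite <- function(which) {
  kld_stop(
    sprintf("covariance matrix '%s' is not positive definite (factorization failed)", which),
    "kld_not_positive_definite"
  )
}

stop_insufficient_sample <- function(message) {
  kld_stop(message, "kld_insufficient_sample")
}

stop_estimation_failure <- function(message) {
  kld_stop(message, "kld_estimation_failure")
}

stop_internal <- function(message) {
  kld_stop(message, "kld_internal_error")
}

# Run expr with a local, restored-on-exit RNG state seeded at `seed`.
# Keeps every stochastic routine reproducible without clobbering the
# caller's random stream.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Derive k child seeds from one parent seed; used so that parallel or
# sequential replicates get independent, reproducible substreams.
derive_seeds <- function(seed, k) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
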