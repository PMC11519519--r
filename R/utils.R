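# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Spawn `n` reproducible sub-seeds from one master seed; keeps every derived
# seed inside the 32-bit integer range.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, msg, class = "scsignal_error", data = list()) {
  cond <- structure(
    class = c(class, "error", "condition"),
    list(message = sprintf("[%s] %s", stage, msg), call = sys.call(-1), data = data)
  )
  stop(cond)
}
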