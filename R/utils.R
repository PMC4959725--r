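# Internal helpers: local RNG scoping and deterministic sub-stream seeds.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
# A NULL seed leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  force(code)
}

# Derive the k-th per-stage seed from a top-level seed. Lehmer-style step
# keeps results in (0, 2^31 - 1) so they remain valid 32-bit R seeds.
substream_seed <- function(seed, k) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m) + 1
  for (i in seq_len(k)) s <- (s * 48271) %% m
  as.integer(s)
}

stop_input <- function(...) {
  stop(structure(
    class = c("kernelscreen_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input(name, " must be a single finite number")
  }
  invisible(x)
}
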