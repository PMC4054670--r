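# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a key
#'
#' Mixes a master integer seed with one or more keys (strings or integers)
#' into a new seed in [0, 2^31 - 2]. Used so that every randomised stage and
#' every per-sample draw gets its own stream: adding samples or toggling a
#' stage never perturbs the randomness of another.
#'
#' @param seed integer master seed.
#' @param ... keys (character or integer scalars) identifying the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  keys <- list(...)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (k in keys) {
    codes <- if (is.character(k)) utf8ToInt(k) else as.numeric(k)
    for (v in codes) {
      h <- (h * 31 + (v %% m) + 7) %% m
    }
    h <- (h * 131 + 17) %% m
  }
  as.integer(h)
}

# Evaluate expr with a locally-set RNG seed; global RNG state is restored.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# stopifnot with a formatted message
.fail <- function(...) stop(sprintf(...), call. = FALSE)
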