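# Internal helpers shared across modules.

# Deterministic 31-bit hash of a string (polynomial rolling hash).
# Used to derive per-sample / per-stage seeds that do not depend on the
# order in which objects are processed.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  m <- 2147483647
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Fan a master seed out to a stage- or sample-specific seed (< 2^31).
derive_seed <- function(master_seed, label) {
  m <- 2147483647
  as.integer((as.numeric(master_seed) %% m * 48271 + stable_hash(label)) %% m)
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
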