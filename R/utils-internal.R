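# Internal helpers: seeded sub-streams and RNG hygiene.

# Derive a deterministic 31-bit sub-seed from a master seed and a sequence of
# integer/string keys. Keeps all arithmetic below 2^53 so doubles are exact.
derive_seed <- function(master, ...) {
  keys <- list(...)
  m <- 2147483629 # largest prime < 2^31
  h <- (abs(as.numeric(master)) + 1) %% m
  for (k in keys) {
    if (is.character(k)) {
      k <- sum(as.numeric(utf8ToInt(k)) * seq_along(utf8ToInt(k)))
    }
    h <- (h * 69069 + (abs(as.numeric(k)) + 1) * 7919) %% m
    h <- (h * 48271) %% m
  }
  as.integer(h %% 2147483646L) + 1L
}

# Evaluate `code` under a given seed without disturbing the caller's RNG state.
local_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# FNV-1a hash of a character scalar, hex string; used to fingerprint run configurations.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30 # keep in int range
    h <- (as.numeric(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
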