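# internal helpers

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic substream seeds: keeps every participant / component on its
# own stream so adding one does not perturb the others. Stays below 2^31.
derive_seed <- function(seed, k) {
  ((as.numeric(seed) %% 100003) * 20011 + 7 * k) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

# FNV-1a 32-bit hash of a string; used for config digests in run manifests.
# Arithmetic is done in doubles split at 16 bits, since R's bitwXor cannot
# hold unsigned 32-bit values and a direct multiply would lose precision.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low8 <- h %% 256
    h <- h - low8 + bitwXor(as.integer(low8), b)
    hi <- floor(h / 65536)
    lo <- h %% 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
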