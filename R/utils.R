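# Small shared helpers.

# 32-bit FNV-1a hash of a character string, returned as 8 hex digits.
# Used for lightweight fingerprints in manifests and sidecars (we avoid a
# cryptographic-hash dependency; collisions only risk a missed mismatch
# warning, never a wrong number).
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h a double throughout
    # since it exceeds .Machine$integer.max
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # multiply by 16777619 mod 2^32 without overflowing doubles:
    # split h into high/low 16-bit halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # format as 8 hex digits (h is a double; split for sprintf's %x on ints)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-score a vector or the columns of a matrix (sample sd, denominator n-1).
zscale <- function(x) {
  if (is.matrix(x)) {
    mu <- colMeans(x)
    sd <- apply(x, 2L, stats::sd)
    sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")
  } else {
    (x - mean(x)) / stats::sd(x)
  }
}

stamp <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
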