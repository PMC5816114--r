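# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Ramanujan's second approximation for the perimeter of an ellipse with
# semi-axes a and b; exact to O(h^10), ample for rasterized objects.
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# FNV-1a hash of a character scalar, returned as 8 hex digits. Used to stamp
# report files with the configuration they came from.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor only touches the low byte because b < 256; h stays a double
    lo8 <- h %% 256
    h <- (h - lo8) + bitwXor(as.integer(lo8), b)
    # multiply by the FNV prime mod 2^32 without losing double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * p) + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
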