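## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never clobber the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Derive a stage-specific substream seed from a top-level seed.
## Keeps every derived seed in the 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- fnv1a32(paste0(stage, ":", as.integer(seed)))
  as.integer(h %% 2147483647)
}

## FNV-1a 32-bit hash of a string, done in double arithmetic (exact below
## 2^53) and reduced mod 2^32 after each multiply.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  ## bitwXor works on 32-bit signed ints; route through [0, 2^31) halves
  hi <- a %/% 2147483648
  lo <- a %% 2147483648
  lo2 <- bitwXor(as.integer(lo %% 2147483648), as.integer(b))
  hi * 2147483648 + (lo2 %% 2147483648)
}

## Short hex digest of an R object (used to stamp run configs in outputs).
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- fnv1a32(as.character(s))
  ## format in two 16-bit halves: h can exceed the signed-integer range
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## Band index <-> elevation conversions for a regular band design.
band_elevations <- function(base_elevation, band_step, n_bands) {
  base_elevation + band_step * (seq_len(n_bands) - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
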