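#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a private RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. All stochastic operations in the package go
# through this so determinism never depends on ambient RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically split one user-facing seed into per-stage seeds, so that
# e.g. simulation and cross-validation consume independent streams. Result
# stays inside the 32-bit signed range R requires of set.seed().
derive_seed <- function(seed, tag) {
  h <- fnv1a32(paste0(tag, ":", as.integer(seed)))
  as.integer(h %% 2147483647L) + 1L
}

# 32-bit FNV-1a over a character scalar, done in double precision (R has no
# native unsigned 32-bit integer). Used for seed splitting and config hashes.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor of two numbers interpreted as unsigned 32-bit values
bitwXor32 <- function(a, b) {
  ra <- a %% 4294967296
  rb <- b %% 4294967296
  hi <- bitwXor(floor(ra / 65536), floor(rb / 65536))
  lo <- bitwXor(ra %% 65536, rb %% 65536)
  hi * 65536 + lo
}

#' Hash a configuration object
#'
#' Stable 32-bit FNV-1a hash of the object's canonical JSON serialization,
#' recorded in every results report so a report can be traced to the exact
#' configuration that produced it.
#'
#' @param x A list-like configuration object.
#' @return Hexadecimal hash string.
#' @export
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- fnv1a32(as.character(json))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_peakfluo <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
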