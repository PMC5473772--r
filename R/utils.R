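#' @keywords internal
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Derive a named RNG substream seed from a top-level seed
#'
#' All randomness in the package flows from a single top-level seed. Each
#' stage (cell sampling, rendering, per-regime simulation, ...) draws from
#' its own substream whose seed is a deterministic function of the top-level
#' seed and the stage name, so that changing parameters of one stage never
#' perturbs the random draws of another.
#'
#' @param seed integer top-level seed.
#' @param name character stage name.
#' @return an integer seed < 2^31, deterministic in `(seed, name)`.
#' @export
#' @examples
#' substream_seed(1, "render") != substream_seed(1, "sample")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- fnv1a(paste0(name, ":", format(seed, scientific = FALSE)))
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

# 32-bit FNV-1a over a UTF-8 string, in numeric arithmetic (no integer
# overflow); returns a nonnegative numeric < 2^32.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# bitwise xor of two nonnegative numerics < 2^32
xor32 <- function(a, b) {
  r <- 0
  p <- 1
  while (a > 0 || b > 0) {
    r <- r + p * as.numeric(xor(a %% 2 >= 1, b %% 2 >= 1))
    a <- a %/% 2
    b <- b %/% 2
    p <- p * 2
  }
  r
}

#' Hash a configuration object for provenance logging
#'
#' @param x any serialisable R object.
#' @return hex string of a 32-bit FNV-1a hash of the object's deparsed form.
#' @export
config_hash <- function(x) {
  h <- fnv1a(paste(deparse(x), collapse = "\n"))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
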