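#' @importFrom stats quantile runif setNames phyper rbinom
#' @importFrom utils head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Encode a DNA string as integers 1..4 (A,C,G,T); N and anything else -> NA.
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  m <- match(v, DNA_BASES)
  m
}

decode_dna <- function(code) {
  out <- DNA_BASES[code]
  out[is.na(code)] <- "N"
  paste(out, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Keeps `N` as `N`; case-insensitive input, uppercase output.
#'
#' @param x single DNA string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Reverse complement of an integer-encoded sequence (NA preserved).
revcomp_code <- function(code) rev(5L - code)

# Deterministic polynomial hash of a string, folded into [0, 2^31 - 20).
# Used to derive per-candidate sampler seeds independent of pool order.
# (Multiplier and modulus are co-prime; doubles hold all intermediates
# exactly since h * 127 + 255 < 2^38.)
str_hash31 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) {
    h <- (h * 127 + b) %% 2147483629
  }
  as.integer(h)
}

derive_seed <- function(global_seed, ...) {
  key <- paste(global_seed, ..., sep = "\r")
  str_hash31(key)
}

# Truncate (not round) a proportion to a percentage with 2 decimals.
# A tiny epsilon guards against 0.145 representing as 14.499999... .
truncate_pct <- function(ratio, digits = 2L) {
  scale <- 10^digits
  floor(ratio * 100 * scale + 1e-9) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_seedmotif <- function(msg, class) {
  stop(structure(
    class = c(class, "seedmotif_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
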