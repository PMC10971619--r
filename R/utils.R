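#' @keywords internal
"_PACKAGE"

# Base-level sequence helpers shared across modules. Sequences are plain
# upper-case character scalars over {A,C,G,T,N}; features use 0-based
# half-open coordinates on the forward strand.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' @param x character scalar over IUPAC DNA letters (at least A/C/G/T/N).
#' @return the reverse complement, same case handling (input is upper-cased).
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  comp <- chartr("ACGTNRYKMSWBDHV", "TGCANYRMKSWVHDB", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' @keywords internal
seq_to_int <- function(x) {
  # A=1 C=2 G=3 T=4, anything else NA; used by the tRNA scanner
  m <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  unname(m[strsplit(toupper(x), "", fixed = TRUE)[[1L]]])
}

#' @keywords internal
assert_dna <- function(x, allow_n = TRUE, what = "sequence") {
  chars <- unique(strsplit(toupper(x), "", fixed = TRUE)[[1L]])
  ok <- c(DNA_BASES, if (allow_n) "N")
  bad <- setdiff(chars, ok)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-DNA symbol(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Run code under a fixed RNG seed, leaving the caller's RNG state untouched.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Extract a possibly origin-wrapping substring from a circular sequence.
# start 0-based inclusive, end 0-based exclusive; end <= start means the
# span runs through the origin.
#' @keywords internal
circular_substr <- function(sequence, start, end, wraps = FALSE) {
  L <- nchar(sequence)
  if (!wraps) return(substr(sequence, start + 1L, end))
  paste0(substr(sequence, start + 1L, L), substr(sequence, 1L, end))
}
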