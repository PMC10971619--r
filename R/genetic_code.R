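# Genetic-code handling. Everything downstream (codon statistics, anticodon
# decoding, tRNA candidate annotation) consumes the list returned by
# genetic_code(); only the construction leans on Biostrings' code tables.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Stop")

#' Genetic code table
#'
#' Builds the codon table used by all codon-usage statistics. The default,
#' NCBI translation table 5 (invertebrate mitochondrial), is the code under
#' which insect mitochondrial protein-coding genes are read: AGA/AGG encode
#' Ser (giving an eight-codon Ser family), ATA encodes Met and TGA Trp, so
#' the table has 62 sense codons and two stops (TAA, TAG).
#'
#' @param table_id integer NCBI translation table id (default 5).
#' @return an object of class \code{genetic_code}: list with \code{table_id},
#'   \code{map} (named character of 64 codons to one-letter amino acids,
#'   \code{"*"} for stops), \code{stops}, \code{sense} (sense codons) and
#'   \code{families} (list of synonymous codon sets, one per amino acid).
#' @export
#' @examples
#' code <- genetic_code(5)
#' length(code$sense)  # 62
genetic_code <- function(table_id = 5L) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  map <- map[order(names(map))]
  stops <- names(map)[map == "*"]
  sense <- names(map)[map != "*"]
  families <- split(sense, map[sense])
  structure(
    list(table_id = as.integer(table_id), map = map, stops = stops,
         sense = sense, families = families),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("Genetic code table %d: %d sense codons, %d stops (%s), %d amino-acid families\n",
              x$table_id, length(x$sense), length(x$stops),
              paste(x$stops, collapse = ","), length(x$families)))
  invisible(x)
}

#' Decode a tRNA anticodon to its amino acid
#'
#' The anticodon, written 5'-3' on the tRNA sense strand, pairs with the
#' codon read 5'-3' on the mRNA; the codon is therefore the reverse
#' complement of the anticodon. Under table 5 the anticodon AAT decodes the
#' codon ATT, i.e. Ile -- the identity of the putative tRNA gene found in
#' Tetrigidae tRNA-Ser/nad1 spacers.
#'
#' @param anticodon 3-mer over A/C/G/T (T used for U).
#' @param code a \code{genetic_code}.
#' @return three-letter amino-acid name, or "Stop".
#' @export
#' @examples
#' decode_anticodon("AAT")  # "Ile"
decode_anticodon <- function(anticodon, code = genetic_code(5L)) {
  stopifnot(is.character(anticodon), length(anticodon) == 1L)
  anticodon <- toupper(chartr("U", "T", anticodon))
  if (nchar(anticodon) != 3L)
    stop("anticodon must be a 3-mer", call. = FALSE)
  assert_dna(anticodon, allow_n = FALSE, what = "anticodon")
  codon <- revcomp(anticodon)
  unname(AA3[code$map[[codon]]])
}
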