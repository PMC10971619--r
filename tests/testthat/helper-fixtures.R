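# Shared fixtures: tiny hand-built records and base distributions used
# across the suite. Everything is generated in code; no files on disk.

AT_PROBS <- c(A = 0.40, C = 0.16, G = 0.11, T = 0.33)

# A 6-bp circular toy with one feature per orientation case.
toy_record <- function() {
  feats <- rbind(
    gene_features("cox1", "PCG", 2L, 5L, "+"),
    gene_features("nad1", "PCG", 2L, 5L, "-"),
    gene_features("trnI", "tRNA", 4L, 2L, "+", wraps_origin = TRUE,
                  anticodon = "GAT"))
  mitogenome_record("toy", "AACGTT", feats, circular = TRUE)
}

# A small annotated circular genome with controlled gap structure:
# geneA [0,100), gap of `gap` nt, geneB, then a wrap-around spacer.
gapped_record <- function(gap, L = 400L, seed = 1L) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), L, TRUE, AT_PROBS), collapse = "")
  feats <- rbind(
    gene_features("trnS2", "tRNA", 0L, 100L, "+", anticodon = "TGA"),
    gene_features("nad1", "PCG", 100L + gap, 300L, "-"))
  mitogenome_record("gapped", s, feats, circular = TRUE)
}

random_dna <- function(n, probs = AT_PROBS, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(probs), n, TRUE, probs), collapse = "")
}

# Independent codon recount used as oracle against count_codons(): reads
# non-overlapping triplets from position 1, drops the trailing partial
# codon and a terminal stop, skips internal stops and N codons.
oracle_codon_counts <- function(cds_list, code) {
  counts <- stats::setNames(integer(64), names(code$map))
  for (s in cds_list) {
    n3 <- (nchar(s) %/% 3) * 3
    cods <- substring(s, seq(1, n3 - 2, 3), seq(3, n3, 3))
    if (length(cods) && cods[length(cods)] %in% code$stops)
      cods <- cods[-length(cods)]
    cods <- cods[!grepl("N", cods) & !(cods %in% code$stops)]
    for (cd in cods) counts[cd] <- counts[cd] + 1L
  }
  counts
}
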