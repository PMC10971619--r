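# Synthetic annotated mitogenomes with known truth. The generator emulates
# the statistical structure the comparative analyses assume -- an AT-rich
# (>70%) circular genome of ~15 kb carrying 37 genes in the ancestral
# insect mitochondrial order (13 PCGs, 22 tRNAs, 2 rRNAs, one control
# region >= 200 nt), A > T and C > G usage, 9 PCGs + 14 tRNAs on the major
# strand, codon-resolved PCG emission with programmable GC3 and GC12 (so a
# chosen neutrality relationship can be wired in), canonical cloverleaf
# tRNAs, and an optional unannotated tRNA implant in the tRNA-Ser/nad1
# spacer -- so every downstream stage has a recovery oracle.

TRNA_ANTICODONS <- c(
  trnA = "TGC", trnR = "TCG", trnN = "GTT", trnD = "GTC", trnC = "GCA",
  trnE = "TTC", trnQ = "TTG", trnG = "TCC", trnH = "GTG", trnI = "GAT",
  trnL1 = "TAG", trnL2 = "TAA", trnK = "CTT", trnM = "CAT", trnF = "GAA",
  trnP = "TGG", trnS1 = "GCT", trnS2 = "TGA", trnT = "TGT", trnW = "TCA",
  trnY = "GTA", trnV = "TAC")

#' Default 37-gene insect mitochondrial template
#'
#' The ancestral insect gene order with 9 PCGs and 14 tRNAs on the major
#' strand, both rRNAs on the minor strand, and the control region between
#' rrnS and trnI. PCG lengths (terminal stop included) total 11,112 bp,
#' inside the range observed across the four Tetrigidae study taxa. The
#' template is data, not code: pass a modified copy to the simulator to
#' change layout.
#'
#' @return data.frame with columns \code{name}, \code{kind}, \code{length},
#'   \code{strand}, \code{anticodon}.
#' @export
default_gene_template <- function() {
  pcg_len <- c(nad2 = 1023, cox1 = 1536, cox2 = 684, atp8 = 159, atp6 = 675,
               cox3 = 786, nad3 = 351, nad5 = 1674, nad4 = 1338, nad4l = 291,
               nad6 = 522, cob = 1134, nad1 = 939)
  order_tab <- list(
    c("trnI", "tRNA", "+"), c("trnQ", "tRNA", "-"), c("trnM", "tRNA", "+"),
    c("nad2", "PCG", "+"), c("trnW", "tRNA", "+"), c("trnC", "tRNA", "-"),
    c("trnY", "tRNA", "-"), c("cox1", "PCG", "+"), c("trnL2", "tRNA", "+"),
    c("cox2", "PCG", "+"), c("trnK", "tRNA", "+"), c("trnD", "tRNA", "+"),
    c("atp8", "PCG", "+"), c("atp6", "PCG", "+"), c("cox3", "PCG", "+"),
    c("trnG", "tRNA", "+"), c("nad3", "PCG", "+"), c("trnA", "tRNA", "+"),
    c("trnR", "tRNA", "+"), c("trnN", "tRNA", "+"), c("trnS1", "tRNA", "+"),
    c("trnE", "tRNA", "+"), c("trnF", "tRNA", "-"), c("nad5", "PCG", "-"),
    c("trnH", "tRNA", "-"), c("nad4", "PCG", "-"), c("nad4l", "PCG", "-"),
    c("trnT", "tRNA", "+"), c("trnP", "tRNA", "-"), c("nad6", "PCG", "+"),
    c("cob", "PCG", "+"), c("trnS2", "tRNA", "+"), c("nad1", "PCG", "-"),
    c("trnL1", "tRNA", "-"), c("rrnL", "rRNA", "-"), c("trnV", "tRNA", "-"),
    c("rrnS", "rRNA", "-"), c("control_region", "noncoding", "+"))
  df <- data.frame(name = vapply(order_tab, `[[`, character(1), 1L),
                   kind = vapply(order_tab, `[[`, character(1), 2L),
                   strand = vapply(order_tab, `[[`, character(1), 3L),
                   stringsAsFactors = FALSE)
  df$length <- ifelse(df$kind == "PCG", pcg_len[df$name],
               ifelse(df$kind == "tRNA", 74L,
               ifelse(df$name == "rrnL", 1300L,
               ifelse(df$name == "rrnS", 780L, NA_integer_))))  # CR sized at run time
  df$anticodon <- ifelse(df$kind == "tRNA", TRNA_ANTICODONS[df$name], NA_character_)
  df
}

#' Simulation parameters
#'
#' Defaults are the study conditions the generator emulates: a ~15.4 kb
#' AT-rich genome (73\% AT, A > T, C > G), GC3 around 15\% with
#' GC12 = 0.23 GC3 + 27.73 (the neutrality relationship observed in the
#' Tetrigidae system), and a >20 nt tRNA-Ser/nad1 spacer.
#'
#' @param seed integer RNG seed.
#' @param genome_length_target target genome length, nt.
#' @param gene_template see \code{\link{default_gene_template}}.
#' @param base_probs named probabilities for A, C, G, T (sum 1; defaults
#'   satisfy pA > pT, pC > pG, pA + pT > 0.7).
#' @param gc3_target GC3 percent programmed into PCG third positions.
#' @param gc12_slope,gc12_intercept neutrality relationship mapping GC3 to
#'   GC12 at first/second positions.
#' @param gc3_range GC3 percent range sampled across taxa (neutrality
#'   simulations).
#' @param trnS_nad1_gap spacer length between trnS2 and nad1 (nt, > 20).
#' @param spacer_range range of ordinary intergenic spacer lengths.
#' @param cr_min minimum control-region length.
#' @param implant_trna NULL, or list(upstream, downstream, anticodon,
#'   length) for an unannotated tRNA implant in the named spacer.
#' @param n_taxa number of taxa for multi-taxon simulations.
#' @return list of class \code{sim_params}.
#' @export
sim_params <- function(seed = 1L, genome_length_target = 15400L,
                       gene_template = default_gene_template(),
                       base_probs = c(A = 0.40, C = 0.16, G = 0.11, T = 0.33),
                       gc3_target = 15, gc12_slope = 0.23,
                       gc12_intercept = 27.73, gc3_range = c(8, 30),
                       trnS_nad1_gap = 30L, spacer_range = 0:4,
                       cr_min = 200L, implant_trna = NULL, n_taxa = 5L) {
  stopifnot(abs(sum(base_probs) - 1) < 1e-9)
  p <- list(seed = as.integer(seed), genome_length_target = genome_length_target,
            gene_template = gene_template, base_probs = base_probs,
            gc3_target = gc3_target, gc12_slope = gc12_slope,
            gc12_intercept = gc12_intercept, gc3_range = gc3_range,
            trnS_nad1_gap = as.integer(trnS_nad1_gap),
            spacer_range = spacer_range, cr_min = as.integer(cr_min),
            implant_trna = implant_trna, n_taxa = as.integer(n_taxa))
  gc12 <- p$gc12_slope * p$gc3_target + p$gc12_intercept
  if (p$gc3_target < 0 || p$gc3_target > 100 || gc12 < 0 || gc12 > 100)
    stop("infeasible composition targets: GC3/GC12 outside [0, 100]")
  pcg_len <- gene_template$length[gene_template$kind == "PCG"]
  if (any(pcg_len %% 3L != 0L)) stop("PCG template lengths must be divisible by 3")
  class(p) <- "sim_params"
  p
}

#' @keywords internal
revcomp_if <- function(x, flag) if (flag) revcomp(x) else x

#' @keywords internal
draw_bases <- function(n, probs) {
  if (n <= 0L) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Emit a pool of sense codons with exact (to rounding) GC fractions per
# codon position, then fix any accidental stop codon by an A->T flip at
# position 2 (GC content at every position is unchanged). With
# swap = TRUE the within-class base identities (A vs T, C vs G) are
# mirrored: this emits genes read from the minor strand so that the
# compositional asymmetry holds on the major strand, as in real
# mitogenomes. `gc_counts` (k1, k2, k3) overrides the per-position GC
# counts for exact pooled allocation across gene groups.
#' @keywords internal
emit_codon_pool <- function(n_codons, gc3_pct, gc12_pct, base_probs, code,
                            swap = FALSE, gc_counts = NULL) {
  stopifnot(n_codons > 0L)
  pGC <- base_probs[c("C", "G")] / sum(base_probs[c("C", "G")])
  pAT <- base_probs[c("A", "T")] / sum(base_probs[c("A", "T")])
  if (swap) { pGC <- rev(stats::setNames(pGC, c("G", "C"))); pAT <- rev(stats::setNames(pAT, c("T", "A"))) }
  pos_bases <- function(k) {
    is_gc <- rep(FALSE, n_codons)
    if (k > 0L) is_gc[sample.int(n_codons, k)] <- TRUE
    b <- character(n_codons)
    b[is_gc] <- sample(names(pGC), sum(is_gc), TRUE, prob = pGC)
    b[!is_gc] <- sample(names(pAT), sum(!is_gc), TRUE, prob = pAT)
    b
  }
  if (is.null(gc_counts)) {
    k12 <- round(n_codons * gc12_pct / 100)
    gc_counts <- c(k12, k12, round(n_codons * gc3_pct / 100))
  }
  b1 <- pos_bases(gc_counts[1]); b2 <- pos_bases(gc_counts[2]); b3 <- pos_bases(gc_counts[3])
  codons <- paste0(b1, b2, b3)
  is_stop <- codons %in% code$stops
  if (any(is_stop)) { b2[is_stop] <- "T"; codons <- paste0(b1, b2, b3) }
  codons
}

#' Emit a canonical cloverleaf tRNA gene
#'
#' Fixed canonical geometry -- acceptor 7 bp, 2-nt spacer, D-arm 4 bp/8 nt,
#' 1-nt spacer, anticodon arm 5 bp/7 nt (anticodon at loop positions 3-5),
#' 4-nt variable region, T-arm 5 bp/7 nt, then discriminator + 2 nt --
#' totalling 74 nt, with perfectly Watson-Crick stems so the gene is
#' detectable by construction.
#'
#' @param anticodon 3-mer, 5'-3' on the tRNA sense strand.
#' @param base_probs base distribution for unpaired positions and 5' arms.
#' @return 74-nt DNA string.
#' @export
emit_trna <- function(anticodon, base_probs = c(A = 0.40, C = 0.16, G = 0.11, T = 0.33)) {
  stopifnot(grepl("^[ACGT]{3}$", anticodon))
  arm <- function(n) paste(draw_bases(n, base_probs), collapse = "")
  acc5 <- arm(7L); d5 <- arm(4L); ac5 <- arm(5L); t5 <- arm(5L)
  paste0(acc5, arm(2L),
         d5, arm(8L), revcomp(d5), arm(1L),
         ac5, arm(2L), anticodon, arm(2L), revcomp(ac5),
         arm(4L),
         t5, arm(7L), revcomp(t5),
         revcomp(acc5), arm(3L))
}

#' Simulate an annotated mitogenome with known truth
#'
#' Builds the genome gene-by-gene along the template: PCGs are emitted
#' codon-wise from a pooled allocation so the realized taxon-level GC3 and
#' GC12 match the programmed targets to within rounding; tRNAs are
#' canonical cloverleaves with standard anticodons; the control region is
#' AT-maximal and sized to reach the target genome length; minor-strand
#' genes are inserted reverse-complemented. An optional tRNA implant is
#' placed, unannotated, in the named intergenic spacer and recorded in the
#' truth.
#'
#' @param params a \code{\link{sim_params}}.
#' @param id record identifier.
#' @return list with \code{record} (a \code{mitogenome_record}) and
#'   \code{truth} (coordinates, CDS list, implant position/anticodon,
#'   programmed targets).
#' @export
simulate_mitogenome <- function(params = sim_params(), id = "sim_taxon1") {
  with_seed(params$seed, simulate_mitogenome_impl(params, id))
}

#' @keywords internal
simulate_mitogenome_impl <- function(params, id) {
  tpl <- params$gene_template
  code <- genetic_code(5L)
  gc12_target <- params$gc12_slope * params$gc3_target + params$gc12_intercept

  # pooled codon emission across PCGs (terminal stops appended separately);
  # the GC allocation is exact at the taxon level and split between the
  # major- and minor-strand gene pools, the latter emitted with mirrored
  # A/T and C/G identities so the compositional asymmetry (A > T, C > G)
  # holds on the major strand as in real mitogenomes
  pcg_rows <- which(tpl$kind == "PCG")
  n_cod <- tpl$length[pcg_rows] / 3L - 1L
  on_major <- tpl$strand[pcg_rows] == "+"
  N <- sum(n_cod); Nmaj <- sum(n_cod[on_major])
  k3 <- round(N * params$gc3_target / 100)
  k12 <- round(N * gc12_target / 100)
  split_k <- function(k) { a <- round(k * Nmaj / N); c(major = a, minor = k - a) }
  s3 <- split_k(k3); s1 <- split_k(k12); s2 <- split_k(k12)
  pools <- list(
    major = emit_codon_pool(Nmaj, NA, NA, params$base_probs, code,
                            gc_counts = c(s1[["major"]], s2[["major"]], s3[["major"]])),
    minor = emit_codon_pool(N - Nmaj, NA, NA, params$base_probs, code,
                            swap = TRUE,
                            gc_counts = c(s1[["minor"]], s2[["minor"]], s3[["minor"]])))
  cds <- stats::setNames(vector("list", length(pcg_rows)), tpl$name[pcg_rows])
  off <- c(major = 0L, minor = 0L)
  for (i in seq_along(pcg_rows)) {
    grp <- if (on_major[i]) "major" else "minor"
    cds[[i]] <- paste0(paste(pools[[grp]][(off[[grp]] + 1L):(off[[grp]] + n_cod[i])],
                             collapse = ""), "TAA")
    off[[grp]] <- off[[grp]] + n_cod[i]
  }

  cr_probs <- params$base_probs
  cr_probs[c("C", "G")] <- 0.05 * cr_probs[c("C", "G")] / sum(cr_probs[c("C", "G")])
  cr_probs[c("A", "T")] <- 0.95 * cr_probs[c("A", "T")] / sum(cr_probs[c("A", "T")])

  implant <- params$implant_trna
  implant_truth <- NULL
  pieces <- character(); feats <- list(); pos <- 0L
  for (i in seq_len(nrow(tpl))) {
    g <- tpl[i, ]
    coding <- switch(g$kind,
      PCG = cds[[g$name]],
      tRNA = emit_trna(g$anticodon, params$base_probs),
      # rRNAs are drawn directly on the major strand so the genome-wide
      # asymmetry is independent of their (minor) transcription strand
      rRNA = revcomp_if(paste(draw_bases(g$length, params$base_probs), collapse = ""),
                        g$strand == "-"),
      noncoding = {
        cr_len <- max(params$cr_min, params$genome_length_target - pos)
        paste(draw_bases(cr_len, cr_probs), collapse = "")
      })
    fwd <- if (g$strand == "-") revcomp(coding) else coding
    feats[[length(feats) + 1L]] <- gene_features(
      g$name, g$kind, pos, pos + nchar(fwd), g$strand,
      anticodon = if (g$kind == "tRNA") g$anticodon else NA_character_)
    pieces <- c(pieces, fwd)
    pos <- pos + nchar(fwd)
    # intergenic spacer after this gene (none after the final element)
    if (i < nrow(tpl)) {
      nxt <- tpl$name[i + 1L]
      if (!is.null(implant) && g$name == implant$upstream && nxt == implant$downstream) {
        # a fixed implant sequence (shared across taxa) models the
        # conserved cross-species tRNA; otherwise draw a fresh one
        tr <- if (!is.null(implant$sequence)) implant$sequence
              else emit_trna(implant$anticodon, params$base_probs)
        stopifnot(nchar(tr) == implant$length)
        gap_len <- max(params$trnS_nad1_gap, implant$length + 14L)
        flank5 <- sample(3:(gap_len - implant$length - 3L), 1L)
        flank3 <- gap_len - implant$length - flank5
        gap_seq <- paste0(paste(draw_bases(flank5, params$base_probs), collapse = ""),
                          tr,
                          paste(draw_bases(flank3, params$base_probs), collapse = ""))
        implant_truth <- list(
          upstream = implant$upstream, downstream = implant$downstream,
          gap_start = pos, gap_length = gap_len,
          offset_in_gap = flank5, offset_genome = pos + flank5,
          anticodon = implant$anticodon, length = implant$length,
          strand = "+", sequence = tr)
        pieces <- c(pieces, gap_seq); pos <- pos + gap_len
      } else if (g$name == "trnS2" && nxt == "nad1") {
        sp <- params$trnS_nad1_gap
        pieces <- c(pieces, paste(draw_bases(sp, params$base_probs), collapse = ""))
        pos <- pos + sp
      } else {
        sp <- sample(params$spacer_range, 1L)
        if (sp > 0L) {
          pieces <- c(pieces, paste(draw_bases(sp, params$base_probs), collapse = ""))
          pos <- pos + sp
        }
      }
    }
  }
  record <- mitogenome_record(id, paste(pieces, collapse = ""),
                              do.call(rbind, feats), circular = TRUE,
                              source = paste0("synthetic mitogenome (seed ",
                                              params$seed, ")"))
  truth <- list(id = id, params = params, coords = record$features,
                cds = cds, implant = implant_truth,
                gc3_target = params$gc3_target, gc12_target = gc12_target)
  list(record = record, truth = truth)
}

#' Simulate a set of taxa (one record + truth each)
#'
#' Taxon i is generated from seed \code{params$seed + i - 1} with its GC3
#' drawn uniformly from \code{params$gc3_range} (GC12 follows the
#' programmed neutrality line), so taxa differ in realized composition.
#' When an implant is requested, one implant sequence is drawn up front
#' and shared by all taxa, modelling the conserved cross-species tRNA.
#'
#' @param params a \code{\link{sim_params}}.
#' @return list of \code{list(record, truth)} of length \code{params$n_taxa}.
#' @export
simulate_taxa <- function(params = sim_params()) {
  if (!is.null(params$implant_trna) && is.null(params$implant_trna$sequence))
    params$implant_trna$sequence <- with_seed(
      params$seed * 1000L + 3L,
      emit_trna(params$implant_trna$anticodon, params$base_probs))
  lapply(seq_len(params$n_taxa), function(i) {
    p <- params
    p$seed <- params$seed + i - 1L
    p$gc3_target <- with_seed(p$seed * 1000L + 7L,
                              stats::runif(1, params$gc3_range[1], params$gc3_range[2]))
    simulate_mitogenome(p, id = sprintf("sim_taxon%d", i))
  })
}

#' Simulate per-taxon CDS sets realizing a programmed neutrality line
#'
#' Each taxon draws GC3 uniformly from \code{params$gc3_range} and sets
#' GC12 = slope * GC3 + intercept + Gaussian noise, then emits a CDS pool
#' realizing those targets to within 0.5 percentage points -- input for
#' parameter-recovery tests of \code{\link{neutrality_regression}}.
#'
#' @param params a \code{\link{sim_params}} (slope/intercept/n_taxa used).
#' @param noise_sd Gaussian noise on GC12, percentage points (>= 0).
#' @param n_codons codons emitted per taxon (default 3000).
#' @return list per taxon: \code{taxon}, \code{cds} (single pooled CDS),
#'   \code{gc3_target}, \code{gc12_target}.
#' @export
simulate_taxa_for_neutrality <- function(params = sim_params(), noise_sd = 0,
                                         n_codons = 3000L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(params$n_taxa >= 3L)
  code <- genetic_code(5L)
  with_seed(params$seed, {
    lapply(seq_len(params$n_taxa), function(i) {
      gc3 <- stats::runif(1, params$gc3_range[1], params$gc3_range[2])
      gc12 <- params$gc12_slope * gc3 + params$gc12_intercept +
        stats::rnorm(1, 0, noise_sd)
      gc12 <- min(max(gc12, 0), 100)
      pool <- emit_codon_pool(n_codons, gc3, gc12, params$base_probs, code)
      list(taxon = sprintf("ntaxon%d", i),
           cds = paste(pool, collapse = ""),
           gc3_target = gc3, gc12_target = gc12)
    })
  })
}

# K80 site substitution probabilities at branch length d (subs/site) and
# transition/transversion rate ratio kappa.
#' @keywords internal
k2p_site_probs <- function(d, kappa) {
  e2 <- exp(-4 * d / (kappa + 2))
  e1 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  c(same = 1 / 4 + e2 / 4 + e1 / 2,
    ts = 1 / 4 + e2 / 4 - e1 / 2,
    tv = 1 / 4 - e2 / 4)  # each of the two transversion targets
}

#' Simulate an alignment on a tree under a two-parameter process
#'
#' The root sequence is drawn from \code{base_probs}; substitutions accrue
#' along each branch under a Kimura two-parameter process with
#' transition/transversion rate ratio \code{kappa} (branch lengths in
#' expected substitutions per site). No indels, no rate heterogeneity.
#'
#' @param tree an \code{ape} \code{phylo} with branch lengths.
#' @param length alignment columns (> 0).
#' @param kappa ts/tv rate ratio (default 4).
#' @param base_probs root base distribution (default uniform).
#' @param seed RNG seed.
#' @return named character vector of aligned leaf sequences.
#' @export
simulate_alignment_on_tree <- function(tree, length, kappa = 4,
                                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                                       seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (length <= 0L) stop("zero-length alignment requested")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nnode <- tree$Nnode
    seqs <- matrix(NA_integer_, ntip + nnode, length)
    root <- ntip + 1L
    seqs[root, ] <- match(draw_bases(length, base_probs), DNA_BASES)
    ts_partner <- c(3L, 4L, 1L, 2L)
    tv1 <- c(2L, 1L, 2L, 1L); tv2 <- c(4L, 3L, 4L, 3L)
    tree_cw <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tree_cw$edge))) {
      par <- tree_cw$edge[e, 1L]; child <- tree_cw$edge[e, 2L]
      d <- tree_cw$edge.length[e]
      pr <- k2p_site_probs(d, kappa)
      x <- seqs[par, ]
      u <- stats::runif(length)
      y <- x
      sel_ts <- u < pr[["ts"]]
      sel_tv1 <- !sel_ts & u < pr[["ts"]] + pr[["tv"]]
      sel_tv2 <- !sel_ts & !sel_tv1 & u < pr[["ts"]] + 2 * pr[["tv"]]
      y[sel_ts] <- ts_partner[x[sel_ts]]
      y[sel_tv1] <- tv1[x[sel_tv1]]
      y[sel_tv2] <- tv2[x[sel_tv2]]
      seqs[child, ] <- y
    }
    out <- apply(seqs[seq_len(ntip), , drop = FALSE], 1L,
                 function(r) paste(DNA_BASES[r], collapse = ""))
    stats::setNames(out, tree$tip.label)
  })
}
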