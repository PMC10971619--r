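# Codon-usage-bias statistics under the invertebrate mitochondrial code:
# codon counting, RSCU, Wright's effective number of codons (ENC) with its
# null expectation, positional GC content, the GC12-on-GC3 neutrality
# regression, and clustering of RSCU matrices.

#' Count codons across a set of coding sequences
#'
#' Codons are read in frame from position 0 of each CDS. A trailing 1-2 nt
#' incomplete codon is dropped; a terminal stop codon is excluded from the
#' counts; internal stops and N-containing codons are tallied separately as
#' quality flags and excluded from \code{n_codons}.
#'
#' @param cds_list character vector/list of in-frame CDS (each >= 3 nt).
#' @param code a \code{\link{genetic_code}}.
#' @param taxon identifier attached to the table.
#' @param genes_included optional gene names (defaults to names of cds_list).
#' @return object of class \code{codon_count_table}: \code{taxon},
#'   \code{counts} (named 64-vector, sense codons only carry counts),
#'   \code{n_codons}, \code{genes_included}, \code{total_pcg_length},
#'   \code{internal_stops}, \code{n_ambiguous}.
#' @export
count_codons <- function(cds_list, code = genetic_code(5L), taxon = "",
                         genes_included = NULL) {
  cds_list <- as.list(cds_list)
  if (length(cds_list) == 0L) stop("empty CDS list")
  if (is.null(genes_included)) genes_included <- names(cds_list)
  all_codons <- names(code$map)
  counts <- stats::setNames(integer(64L), all_codons)
  internal_stops <- 0L; n_ambiguous <- 0L; total_len <- 0L
  for (i in seq_along(cds_list)) {
    s <- toupper(cds_list[[i]])
    assert_dna(s, allow_n = TRUE, what = sprintf("CDS %d", i))
    if (nchar(s) < 3L) stop(sprintf("CDS %d shorter than one codon", i))
    total_len <- total_len + nchar(s)
    nc <- nchar(s) %/% 3L
    cods <- substring(s, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
    if (cods[nc] %in% code$stops) cods <- cods[-nc]
    amb <- grepl("N", cods, fixed = TRUE)
    n_ambiguous <- n_ambiguous + sum(amb)
    cods <- cods[!amb]
    is_stop <- cods %in% code$stops
    internal_stops <- internal_stops + sum(is_stop)
    tab <- table(cods[!is_stop])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(list(
    taxon = taxon, counts = counts,
    n_codons = sum(counts[code$sense]),
    genes_included = genes_included,
    total_pcg_length = total_len,
    internal_stops = internal_stops,
    n_ambiguous = n_ambiguous
  ), class = "codon_count_table")
}

#' @export
print.codon_count_table <- function(x, ...) {
  cat(sprintf("<codon_count_table> %s: %d codons over %d gene(s), %d bp; %d internal stop(s)\n",
              if (nzchar(x$taxon)) x$taxon else "(unnamed)",
              x$n_codons, length(x$genes_included), x$total_pcg_length,
              x$internal_stops))
  invisible(x)
}

#' @keywords internal
as_codon_counts <- function(x, code) {
  if (inherits(x, "codon_count_table")) return(x$counts)
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- stats::setNames(numeric(64L), names(code$map))
    counts[names(x)] <- x
    return(counts)
  }
  stop("expected a codon_count_table or a named codon count vector")
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the mean count of its
#' synonymous family: 1 means no bias, values above 1 mark favoured codons.
#' A family with zero total usage yields RSCU 0 for all members and its
#' amino acid is listed in the \code{empty_families} attribute; a
#' single-codon family is
#' 1 whenever used. By construction the RSCU values of a family sum to the
#' family size.
#'
#' @param x a \code{codon_count_table} or named count vector.
#' @param code a \code{\link{genetic_code}}.
#' @return named numeric over sense codons (stop codons excluded).
#' @export
rscu <- function(x, code = genetic_code(5L)) {
  counts <- as_codon_counts(x, code)
  if (sum(counts[code$sense]) <= 0) stop("no sense codons counted")
  out <- stats::setNames(numeric(length(code$sense)), code$sense)
  empty <- character()
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    tot <- sum(counts[fam])
    if (tot == 0) {
      out[fam] <- 0
      empty <- c(empty, aa)
    } else {
      out[fam] <- counts[fam] / (tot / length(fam))
    }
  }
  attr(out, "empty_families") <- empty
  out
}

#' Effective number of codons (ENC)
#'
#' Wright's generalized estimator of how far codon usage departs from
#' uniform use of synonyms: it runs from the number of amino-acid families
#' (each amino acid uses a single codon) up to the number of sense codons
#' (62 under table 5, no bias). Per synonymous family of size k with n
#' counted codons and usage frequencies p_i, the homozygosity is estimated
#' as F = (n * sum(p_i^2) - 1)/(n - 1); families are grouped by size and
#' ENC = sum over size classes of N_k / mean(F_k). Families with n < 2 are
#' imputed from the mean F of their size class (Wright's rule); an empty
#' size class of size 3 is interpolated from the size-2 and size-4 classes,
#' any other empty class falls back to the uniform value 1/k.
#'
#' @param x a \code{codon_count_table} or named count vector.
#' @param code a \code{\link{genetic_code}}.
#' @return ENC value in (0, number of sense codons].
#' @export
enc <- function(x, code = genetic_code(5L)) {
  counts <- as_codon_counts(x, code)
  fam_stats <- lapply(code$families, function(fam) {
    n <- sum(counts[fam])
    k <- length(fam)
    if (k == 1L) return(list(k = k, n = n, F = 1))
    if (n < 2) return(list(k = k, n = n, F = NA_real_))
    p <- counts[fam] / n
    list(k = k, n = n, F = (n * sum(p^2) - 1) / (n - 1))
  })
  ks <- vapply(fam_stats, `[[`, numeric(1), "k")
  Fs <- vapply(fam_stats, `[[`, numeric(1), "F")
  if (all(is.na(Fs[ks > 1L]))) stop("insufficient codons: no family has n >= 2")
  sizes <- sort(unique(ks))
  fbar <- stats::setNames(rep(NA_real_, length(sizes)), sizes)
  for (k in sizes) {
    v <- Fs[ks == k & !is.na(Fs)]
    if (length(v) > 0L) fbar[as.character(k)] <- mean(v)
  }
  for (k in sizes) {
    key <- as.character(k)
    if (is.na(fbar[key])) {
      if (k == 3L && !is.na(fbar["2"]) && !is.na(fbar["4"]))
        fbar[key] <- (fbar[["2"]] + fbar[["4"]]) / 2
      else fbar[key] <- 1 / k
    }
  }
  # guard against a degenerate mean homozygosity of zero
  fbar[fbar <= 0] <- 1 / as.numeric(names(fbar)[fbar <= 0])
  n_k <- table(ks)
  value <- sum(as.numeric(n_k) / fbar[names(n_k)])
  min(max(value, .Machine$double.eps), length(code$sense))
}

#' Wright's null ENC expectation from GC3
#'
#' Expected ENC for a gene whose codon bias is produced purely by
#' compositional (mutational) pressure at third positions:
#' ENC*(s) = 2 + s + 29 / (s^2 + (1-s)^2), with s the GC3 fraction.
#'
#' @param gc3_fraction GC3 as a proportion in [0, 1] (vectorised).
#' @return expected ENC.
#' @export
#' @examples
#' enc_expected(0.5)  # 60.5
enc_expected <- function(gc3_fraction) {
  stopifnot(all(gc3_fraction >= 0 & gc3_fraction <= 1))
  s <- gc3_fraction
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Positional GC content of counted codons
#'
#' GC percentage at each codon position over exactly the codons retained by
#' \code{\link{count_codons}} (terminal stops, internal stops and ambiguous
#' codons excluded), plus GC12 = (GC1 + GC2)/2 -- the quantities behind the
#' neutrality plot.
#'
#' @param x a CDS list, \code{codon_count_table}, or named count vector.
#' @param code a \code{\link{genetic_code}}.
#' @return list with \code{gc1}, \code{gc2}, \code{gc3}, \code{gc12}
#'   (percent).
#' @export
positional_gc <- function(x, code = genetic_code(5L)) {
  if (!inherits(x, "codon_count_table") && !(is.numeric(x) && !is.null(names(x))))
    x <- count_codons(x, code)
  counts <- as_codon_counts(x, code)
  n <- sum(counts[code$sense])
  if (n == 0) stop("zero counted codons")
  gc_at <- function(pos) {
    b <- substr(code$sense, pos, pos)
    100 * sum(counts[code$sense][b %in% c("G", "C")]) / n
  }
  gc1 <- gc_at(1L); gc2 <- gc_at(2L); gc3 <- gc_at(3L)
  list(gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2)
}

#' Per-taxon codon usage summary
#'
#' @param cds_list CDS list for one taxon.
#' @param code a \code{\link{genetic_code}}.
#' @param taxon identifier.
#' @return list of class \code{codon_usage_summary}: \code{taxon},
#'   \code{rscu}, \code{enc}, \code{gc1..gc3}, \code{gc12}, \code{n_codons},
#'   \code{counts} (the underlying \code{codon_count_table}).
#' @export
codon_usage_summary <- function(cds_list, code = genetic_code(5L), taxon = "") {
  ct <- count_codons(cds_list, code, taxon = taxon)
  pg <- positional_gc(ct, code)
  structure(list(taxon = taxon, rscu = rscu(ct, code), enc = enc(ct, code),
                 gc1 = pg$gc1, gc2 = pg$gc2, gc3 = pg$gc3, gc12 = pg$gc12,
                 n_codons = ct$n_codons, counts = ct),
            class = "codon_usage_summary")
}

#' @export
print.codon_usage_summary <- function(x, ...) {
  cat(sprintf("<codon_usage_summary> %s: ENC %.2f | GC1 %.2f GC2 %.2f GC3 %.2f GC12 %.2f | %d codons\n",
              if (nzchar(x$taxon)) x$taxon else "(unnamed)",
              x$enc, x$gc1, x$gc2, x$gc3, x$gc12, x$n_codons))
  invisible(x)
}

#' GC12-on-GC3 neutrality regression
#'
#' Ordinary least squares of GC12 on GC3 across taxa (or genes). A slope
#' near 1 indicates that directional mutation pressure alone shapes all
#' three codon positions (drift regime); a slope well below 1 indicates
#' that first/second positions are shielded by selection while mutation
#' bias drives GC3. The Tetrigidae study-system fit is y = 0.23x + 27.73.
#'
#' @param gc3,gc12 numeric vectors in percent, or \code{gc3} may be a
#'   data.frame with columns \code{gc3} and \code{gc12}.
#' @param band "confidence" (95\% band of the mean response, default) or
#'   "prediction".
#' @return object of class \code{neutrality_fit}: \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{n_points},
#'   \code{interpretation} ("mutation-bias dominant" when slope < 1),
#'   \code{ci95_band} (function of x returning fit/lwr/upr), \code{model}.
#' @export
neutrality_regression <- function(gc3, gc12 = NULL, band = c("confidence", "prediction")) {
  band <- match.arg(band)
  if (is.data.frame(gc3)) { gc12 <- gc3$gc12; gc3 <- gc3$gc3 }
  stopifnot(length(gc3) == length(gc12))
  if (length(gc3) < 3L) stop("need at least 3 points")
  if (stats::var(gc3) == 0) stop("degenerate regression: GC3 values all identical")
  df <- data.frame(gc3 = gc3, gc12 = gc12)
  fit <- stats::lm(gc12 ~ gc3, data = df)
  co <- stats::coef(fit)
  structure(list(
    slope = unname(co[["gc3"]]),
    intercept = unname(co[["(Intercept)"]]),
    r_squared = summary(fit)$r.squared,
    n_points = length(gc3),
    interpretation = if (co[["gc3"]] < 1) "mutation-bias dominant" else "drift dominant",
    ci95_band = function(x) {
      as.data.frame(stats::predict(fit, newdata = data.frame(gc3 = x),
                                   interval = band, level = 0.95))
    },
    model = fit
  ), class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf("Neutrality regression: GC12 = %.4f * GC3 + %.4f (r^2 = %.3f, n = %d) -- %s\n",
              x$slope, x$intercept, x$r_squared, x$n_points, x$interpretation))
  invisible(x)
}

#' Assemble a taxa-by-codon RSCU matrix
#'
#' @param summaries list of \code{codon_usage_summary} (or of RSCU vectors
#'   named by taxon).
#' @return numeric matrix, rows = taxa, columns = sense codons.
#' @export
rscu_matrix <- function(summaries) {
  vecs <- lapply(summaries, function(s) if (inherits(s, "codon_usage_summary")) s$rscu else s)
  taxa <- vapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    if (inherits(s, "codon_usage_summary") && nzchar(s$taxon)) s$taxon
    else if (!is.null(names(summaries)[i]) && nzchar(names(summaries)[i])) names(summaries)[i]
    else paste0("taxon", i)
  }, character(1))
  mat <- do.call(rbind, lapply(vecs, as.numeric))
  dimnames(mat) <- list(taxa, names(vecs[[1L]]))
  mat
}

#' Cluster an RSCU matrix by rows and columns
#'
#' Agglomerative clustering with average linkage on Euclidean distance, as
#' used for RSCU heatmaps where taxa with similar codon bias group together
#' and unfavoured codons (RSCU < 1) separate from favoured ones. Leaf order
#' is made deterministic by seriating each dendrogram against input index.
#'
#' @param mat numeric matrix (>= 2 rows, >= 2 columns, no missing values).
#' @return list with \code{row_order}, \code{col_order} (leaf orders),
#'   \code{row_hclust}, \code{col_hclust}, and \code{matrix} (reordered).
#' @export
cluster_rscu_matrix <- function(mat) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2L || ncol(mat) < 2L) stop("need at least a 2x2 matrix")
  if (any(is.na(mat))) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value in RSCU matrix at row '%s', column '%s'",
                 rownames(mat)[idx[1L]] %||% idx[1L],
                 colnames(mat)[idx[2L]] %||% idx[2L]))
  }
  hc_r <- stats::hclust(stats::dist(mat, method = "euclidean"), method = "average")
  hc_c <- stats::hclust(stats::dist(t(mat), method = "euclidean"), method = "average")
  list(row_order = hc_r$order, col_order = hc_c$order,
       row_hclust = hc_r, col_hclust = hc_c,
       matrix = mat[hc_r$order, hc_c$order, drop = FALSE])
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
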