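# Extraction of the 13 mitochondrial protein-coding genes, concatenation
# into a partitioned supermatrix for external tree software, and a light
# distance/NJ stage for desk-scale sanity checks. The NJ/K2P tree is
# plumbing for smoke tests, not a substitute for ML/Bayesian inference.

#' Extract the 13 canonical mitochondrial PCGs from annotated records
#'
#' Pulls atp6, atp8, cox1-3, cob, nad1-6 and nad4l per taxon in coding
#' orientation (minor-strand genes reverse-complemented, origin-wrapping
#' genes joined). Gene names are expected to be normalised (the GenBank
#' reader does this); taxa missing a gene are flagged.
#'
#' @param records list of \code{mitogenome_record}.
#' @return a \code{gene_set}: list with \code{genes} (gene -> named
#'   character vector of sequences by taxon), \code{alignment_state}
#'   ("unaligned"), \code{taxa}, and \code{missing} (data.frame taxon/gene).
#' @export
extract_pcg_set <- function(records) {
  if (inherits(records, "mitogenome_record")) records <- list(records)
  taxa <- vapply(records, `[[`, character(1), "id")
  genes <- stats::setNames(
    lapply(PCG_NAMES, function(g) stats::setNames(character(), character())),
    PCG_NAMES)
  missing <- list()
  for (rec in records) {
    f <- rec$features
    pcgs <- f[f$kind == "PCG" & f$name %in% PCG_NAMES, , drop = FALSE]
    if (nrow(pcgs) == 0L)
      stop("record with zero recognizable protein-coding genes: ", rec$id)
    for (g in PCG_NAMES) {
      row <- which(pcgs$name == g)
      if (length(row) == 0L) {
        missing[[length(missing) + 1L]] <- data.frame(taxon = rec$id, gene = g)
      } else {
        genes[[g]][rec$id] <- extract_feature_sequence(rec, pcgs[row[1L], ])
      }
    }
  }
  miss <- if (length(missing) > 0L) do.call(rbind, missing)
          else data.frame(taxon = character(), gene = character())
  if (nrow(miss) > 0L)
    warning("missing: ", paste(unique(paste0(miss$gene, " (", miss$taxon, ")")),
                               collapse = ", "), call. = FALSE)
  structure(list(genes = genes, alignment_state = "unaligned",
                 taxa = taxa, missing = miss),
            class = "gene_set")
}

#' Mark a gene set as aligned
#'
#' Alignment itself is delegated to external tools (e.g. MAFFT); this
#' checks equal within-gene lengths and flips the state flag. Gene sets
#' whose sequences are equal-length by construction (simulated data) can be
#' marked directly.
#'
#' @param genes a \code{gene_set} or a named list of named character
#'   vectors (gene -> taxon -> aligned sequence).
#' @return a \code{gene_set} with \code{alignment_state = "aligned"}.
#' @export
as_aligned_gene_set <- function(genes) {
  if (!inherits(genes, "gene_set")) {
    taxa <- unique(unlist(lapply(genes, names)))
    genes <- structure(list(genes = genes, alignment_state = "unaligned",
                            taxa = taxa,
                            missing = data.frame(taxon = character(), gene = character())),
                       class = "gene_set")
  }
  for (g in names(genes$genes)) {
    lens <- unique(nchar(genes$genes[[g]]))
    if (length(lens) > 1L)
      stop("ragged alignment in gene ", g, ": lengths ",
           paste(lens, collapse = ", "))
  }
  genes$alignment_state <- "aligned"
  genes
}

#' Concatenate aligned genes into a partitioned supermatrix
#'
#' @param genes an aligned \code{gene_set}.
#' @param gene_order order of gene blocks (default: order in the set).
#' @param missing_policy "error" (default) or "gapfill" (absent taxa get
#'   all-gap blocks).
#' @return object of class \code{supermatrix}: \code{taxa}, \code{matrix}
#'   (taxon -> concatenated row), \code{partitions} (data.frame gene /
#'   start / end, 1-based inclusive), \code{total_length}.
#' @export
concatenate <- function(genes, gene_order = NULL, missing_policy = c("error", "gapfill")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(genes, "gene_set"))
  if (genes$alignment_state != "aligned")
    stop("gene set is not aligned; call as_aligned_gene_set() first")
  if (is.null(gene_order)) gene_order <- names(genes$genes)
  stopifnot(all(gene_order %in% names(genes$genes)))
  taxa <- genes$taxa
  parts <- list(); pos <- 0L
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  for (g in gene_order) {
    gs <- genes$genes[[g]]
    len <- unique(nchar(gs))
    if (length(len) != 1L) stop("ragged alignment in gene ", g)
    absent <- setdiff(taxa, names(gs))
    if (length(absent) > 0L) {
      if (missing_policy == "error")
        stop("gene ", g, " missing for taxa: ", paste(absent, collapse = ", "))
      gs[absent] <- strrep("-", len)
    }
    unknown <- setdiff(names(gs), taxa)
    if (length(unknown) > 0L)
      stop("unknown taxa in gene ", g, ": ", paste(unknown, collapse = ", "))
    rows[taxa] <- paste0(rows[taxa], gs[taxa])
    parts[[length(parts) + 1L]] <- data.frame(gene = g, start = pos + 1L,
                                              end = pos + len)
    pos <- pos + len
  }
  structure(list(taxa = taxa, matrix = rows,
                 partitions = do.call(rbind, parts), total_length = pos),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d partitions (%s...)\n",
              length(x$taxa), x$total_length, nrow(x$partitions),
              paste(utils::head(x$partitions$gene, 3L), collapse = ",")))
  invisible(x)
}

#' Slice a supermatrix at a partition
#' @param m a \code{supermatrix}.
#' @param gene partition (gene) name.
#' @return named character vector of the gene block, by taxon.
#' @export
slice_partition <- function(m, gene) {
  p <- m$partitions[m$partitions$gene == gene, ]
  if (nrow(p) != 1L) stop("no such partition: ", gene)
  vapply(m$matrix, substr, character(1), p$start, p$end)
}

# ---- distances and NJ ------------------------------------------------------

#' Pairwise sequence distance
#'
#' Sites with a gap, N or other ambiguity in either sequence are excluded.
#' p-distance is the mismatch proportion over valid sites; K2P corrects for
#' multiple hits with distinct transition/transversion rates:
#' d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)), with P and Q the transition and
#' transversion proportions.
#'
#' @param a,b equal-length DNA strings.
#' @param model "p" (default) or "K2P".
#' @return distance (substitutions per site).
#' @export
pairwise_distance <- function(a, b, model = c("p", "K2P")) {
  model <- match.arg(model)
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  valid <- av %in% DNA_BASES & bv %in% DNA_BASES
  n <- sum(valid)
  if (n == 0L) stop("zero valid sites between sequences")
  av <- av[valid]; bv <- bv[valid]
  mism <- av != bv
  if (model == "p") return(sum(mism) / n)
  purine <- c("A", "G")
  ts <- mism & ((av %in% purine) == (bv %in% purine))
  P <- sum(ts) / n
  Q <- sum(mism & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) stop("saturated: K2P distance undefined")
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Distance matrix over a supermatrix or sequence set
#'
#' @param x a \code{supermatrix} or named character vector of equal-length
#'   sequences.
#' @param model "p" or "K2P".
#' @return symmetric matrix with zero diagonal, class \code{dist_matrix}.
#' @export
distance_matrix <- function(x, model = c("p", "K2P")) {
  model <- match.arg(model)
  seqs <- if (inherits(x, "supermatrix")) x$matrix else x
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- pairwise_distance(seqs[[i]], seqs[[j]], model)
  attr(d, "model") <- model
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei NJ via \code{ape::nj}; negative branch lengths are clamped to
#' zero with a warning. Exact on additive distances; provided as a
#' smoke-test stage only.
#'
#' @param d symmetric distance matrix (>= 3 taxa).
#' @param midpoint_root midpoint-root the result (requires phangorn).
#' @return an \code{ape} \code{phylo} (unrooted unless rooted).
#' @export
nj_tree <- function(d, midpoint_root = FALSE) {
  stopifnot(is.matrix(d))
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("distance matrix is not symmetric")
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0", call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  if (midpoint_root) tree <- phangorn::midpoint(tree)
  tree
}

# ---- writers ---------------------------------------------------------------

#' Write a supermatrix (and partitions) to standard formats
#'
#' Taxon names are sanitised for the dialect (non-alphanumerics to "_");
#' the mapping is returned. Formats: aligned FASTA, relaxed PHYLIP
#' (sequential), NEXUS with a sets block, and a RAxML-style partition file
#' ("DNA, gene = start-end").
#'
#' @param m a \code{supermatrix}.
#' @param prefix path prefix; files get .fasta/.phy/.nex/.partitions.
#' @param formats subset of c("fasta", "phylip", "nexus", "partitions").
#' @return invisibly, a list with \code{files} and the taxon \code{name_map}.
#' @export
write_matrix <- function(m, prefix,
                         formats = c("fasta", "phylip", "nexus", "partitions")) {
  stopifnot(inherits(m, "supermatrix"))
  clean <- gsub("[^A-Za-z0-9_.]", "_", m$taxa)
  if (anyDuplicated(clean)) clean <- make.unique(clean, sep = "_")
  name_map <- stats::setNames(clean, m$taxa)
  files <- character()
  seqs <- stats::setNames(unname(m$matrix), clean)
  if ("fasta" %in% formats) {
    f <- paste0(prefix, ".fasta"); write_fasta(seqs, f); files["fasta"] <- f
  }
  if ("phylip" %in% formats) {
    f <- paste0(prefix, ".phy")
    con <- file(f, "w")
    writeLines(sprintf("%d %d", length(seqs), m$total_length), con)
    writeLines(sprintf("%s  %s", names(seqs), seqs), con)
    close(con)
    files["phylip"] <- f
  }
  if ("nexus" %in% formats) {
    f <- paste0(prefix, ".nex")
    con <- file(f, "w")
    writeLines(c("#NEXUS", "BEGIN DATA;",
                 sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(seqs), m$total_length),
                 "  FORMAT DATATYPE=DNA MISSING=N GAP=-;", "  MATRIX"), con)
    writeLines(sprintf("    %s  %s", names(seqs), seqs), con)
    writeLines(c("  ;", "END;", "", "BEGIN SETS;"), con)
    writeLines(sprintf("  CHARSET %s = %d-%d;", m$partitions$gene,
                       m$partitions$start, m$partitions$end), con)
    writeLines("END;", con)
    close(con)
    files["nexus"] <- f
  }
  if ("partitions" %in% formats) {
    f <- paste0(prefix, ".partitions")
    writeLines(sprintf("DNA, %s = %d-%d", m$partitions$gene,
                       m$partitions$start, m$partitions$end), f)
    files["partitions"] <- f
  }
  invisible(list(files = files, name_map = name_map))
}

#' Read a relaxed sequential PHYLIP alignment
#' @param path file written by \code{\link{write_matrix}}.
#' @return named character vector of sequences.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  body <- lines[-1L][nzchar(trimws(lines[-1L]))]
  parts <- strsplit(trimws(body), "\\s+")
  out <- stats::setNames(vapply(parts, `[[`, character(1), 2L),
                         vapply(parts, `[[`, character(1), 1L))
  if (length(out) != hdr[1L] || any(nchar(out) != hdr[2L]))
    stop("PHYLIP dimensions do not match header")
  out
}

#' Read the CHARSET partitions from a NEXUS sets block
#' @param path NEXUS file written by \code{\link{write_matrix}}.
#' @return data.frame with gene, start, end.
#' @export
read_nexus_partitions <- function(path) {
  lines <- grep("^\\s*CHARSET", readLines(path), value = TRUE)
  m <- regmatches(lines, regexec("CHARSET\\s+(\\S+)\\s*=\\s*([0-9]+)-([0-9]+)", lines))
  data.frame(gene = vapply(m, `[[`, character(1), 2L),
             start = as.integer(vapply(m, `[[`, character(1), 3L)),
             end = as.integer(vapply(m, `[[`, character(1), 4L)))
}
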