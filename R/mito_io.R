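# Data model for circular annotated mitogenomes plus GenBank flat-file and
# FASTA I/O. Internal coordinates are 0-based half-open on the forward
# strand; GenBank's 1-based inclusive coordinates are converted at the I/O
# boundary. An origin-wrapping gene is a single feature with
# wraps_origin = TRUE (start = 0-based start of the 5' span, end = half-open
# end of the 3' span), never two features, so gap scanning and extraction
# keep gene identity.

FEATURE_KINDS <- c("PCG", "tRNA", "rRNA", "noncoding")

PCG_NAMES <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cob",
               "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")

# ---- coordinate conversion -------------------------------------------------

#' Convert GenBank 1-based inclusive coordinates to internal 0-based half-open
#' @param start,end numeric vectors, GenBank convention (start <= end).
#' @return data.frame with columns start, end in the internal convention.
#' @export
gb_to_internal <- function(start, end) data.frame(start = start - 1L, end = end)

#' Convert internal 0-based half-open coordinates to GenBank 1-based inclusive
#' @param start,end numeric vectors, internal convention.
#' @return data.frame with columns start, end in the GenBank convention.
#' @export
internal_to_gb <- function(start, end) data.frame(start = start + 1L, end = end)

# ---- constructors ----------------------------------------------------------

#' Build a gene feature table
#'
#' @param name gene symbols (canonical where possible, e.g. nad1, cox1,
#'   trnS2, rrnL, control_region).
#' @param kind one of "PCG", "tRNA", "rRNA", "noncoding" per feature.
#' @param start,end 0-based half-open forward-strand coordinates. For an
#'   origin-wrapping feature, \code{start} is the 0-based start of the span
#'   running to the sequence end and \code{end} the half-open end of the
#'   span starting at position 0.
#' @param strand "+" (major) or "-" (minor).
#' @param wraps_origin logical, feature spans the replication origin.
#' @param anticodon optional 3-mer for tRNAs (NA allowed, never "").
#' @return data.frame of class unchanged, one row per feature.
#' @export
gene_features <- function(name, kind, start, end, strand = "+",
                          wraps_origin = FALSE, anticodon = NA_character_) {
  df <- data.frame(name = as.character(name), kind = as.character(kind),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), length(name)),
                   wraps_origin = rep_len(as.logical(wraps_origin), length(name)),
                   anticodon = rep_len(as.character(anticodon), length(name)),
                   stringsAsFactors = FALSE)
  bad <- !df$kind %in% FEATURE_KINDS
  if (any(bad)) stop("unknown feature kind: ", paste(unique(df$kind[bad]), collapse = ", "))
  if (any(!is.na(df$anticodon) & df$anticodon == ""))
    stop("anticodon must be a 3-mer or NA, never an empty string")
  df
}

#' Construct an annotated mitogenome record
#'
#' @param id accession / taxon identifier (non-empty).
#' @param sequence DNA string over A/C/G/T/N.
#' @param features a \code{\link{gene_features}} data.frame.
#' @param circular logical, default TRUE.
#' @param translation_table NCBI genetic-code id, default 5.
#' @param source free-text provenance (e.g. organism name).
#' @return object of class \code{mitogenome_record}.
#' @export
mitogenome_record <- function(id, sequence, features = gene_features(character(), character(), integer(), integer()),
                              circular = TRUE, translation_table = 5L,
                              source = "") {
  sequence <- toupper(sequence)
  rec <- structure(
    list(id = id, sequence = sequence, circular = circular,
         features = features, translation_table = as.integer(translation_table),
         source = source),
    class = "mitogenome_record"
  )
  validate_record(rec)
  rec
}

#' Validate a mitogenome record's invariants
#'
#' Checks non-empty identifier and sequence, DNA alphabet, feature kinds and
#' resolvability of every feature coordinate under the circular convention.
#'
#' @param record a \code{mitogenome_record}.
#' @return invisibly TRUE, or an error.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "mitogenome_record"))
  if (!nzchar(record$id)) stop("record identifier is empty")
  L <- nchar(record$sequence)
  if (L == 0L) stop("record sequence is empty")
  assert_dna(record$sequence, allow_n = TRUE, what = paste0("sequence of ", record$id))
  f <- record$features
  if (nrow(f) > 0L) {
    if (any(f$start < 0L | f$start >= L))
      stop("feature start out of range in ", record$id)
    if (any(f$end < 1L | f$end > L))
      stop("feature end out of range in ", record$id)
    if (any(!f$wraps_origin & f$end <= f$start))
      stop("non-wrapping feature with end <= start in ", record$id)
    if (any(f$wraps_origin) && !record$circular)
      stop("origin-wrapping feature on a linear record: ", record$id)
  }
  invisible(TRUE)
}

#' @export
print.mitogenome_record <- function(x, ...) {
  k <- table(factor(x$features$kind, levels = FEATURE_KINDS))
  cat(sprintf("<mitogenome_record> %s: %s bp, %s; %d features (%d PCG, %d tRNA, %d rRNA, %d noncoding)\n",
              x$id, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features), k[["PCG"]], k[["tRNA"]], k[["rRNA"]], k[["noncoding"]]))
  invisible(x)
}

# Forward-strand spans of a feature as a list of c(start, end) half-open
# pairs, in gene (5'->3' on the forward strand) order.
#' @keywords internal
feature_spans <- function(feature, L) {
  if (isTRUE(feature$wraps_origin)) {
    list(c(feature$start, L), c(0L, feature$end))
  } else {
    list(c(feature$start, feature$end))
  }
}

#' Length of a feature in nucleotides
#' @param feature one row of a feature table (list or 1-row data.frame).
#' @param L sequence length of the containing record.
#' @return integer span length.
#' @export
feature_length <- function(feature, L) {
  sum(vapply(feature_spans(feature, L), function(s) s[2] - s[1], numeric(1)))
}

#' Extract a feature's sequence in coding orientation
#'
#' Origin-wrapping spans are concatenated in gene order; minor-strand
#' features are reverse-complemented so the result always reads 5'->3' in
#' coding orientation.
#'
#' @param record a \code{mitogenome_record}.
#' @param feature one row of \code{record$features} (list or 1-row data.frame).
#' @return DNA string.
#' @export
extract_feature_sequence <- function(record, feature) {
  if (is.data.frame(feature)) {
    stopifnot(nrow(feature) == 1L)
    feature <- as.list(feature)
  }
  L <- nchar(record$sequence)
  if (feature$start < 0L || feature$start >= L || feature$end > L)
    stop("feature does not lie within record ", record$id)
  s <- paste(vapply(feature_spans(feature, L),
                    function(sp) substr(record$sequence, sp[1] + 1L, sp[2]),
                    character(1)),
             collapse = "")
  if (identical(feature$strand, "-")) s <- revcomp(s)
  s
}

#' Summarise gene content of a record
#' @param record a \code{mitogenome_record}.
#' @return named integer vector with counts of PCG, tRNA, rRNA, noncoding
#'   features and \code{genes} (all but noncoding).
#' @export
gene_content <- function(record) {
  k <- table(factor(record$features$kind, levels = FEATURE_KINDS))
  c(PCG = unname(k[["PCG"]]), tRNA = unname(k[["tRNA"]]),
    rRNA = unname(k[["rRNA"]]), noncoding = unname(k[["noncoding"]]),
    genes = unname(sum(k) - k[["noncoding"]]))
}

# ---- gene-name normalisation ----------------------------------------------

.synonym_env <- new.env(parent = emptyenv())

#' Gene-name synonym table
#'
#' GenBank annotation vocabulary is inconsistent across submitters (ND1 /
#' nad1 / NADH dehydrogenase subunit 1, COI / cox1, 16S / rrnL, ...). The
#' bundled table maps common variants to canonical symbols; it is plain TSV
#' under \code{inst/extdata} and user-replaceable via \code{path}.
#'
#' @param path optional TSV with columns \code{synonym}, \code{canonical}.
#' @return named character vector: upper-cased synonym -> canonical.
#' @export
gene_synonyms <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.synonym_env$table)) return(.synonym_env$table)
    path <- system.file("extdata", "gene_synonyms.tsv", package = "tetrimito")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- stats::setNames(tab$canonical, toupper(tab$synonym))
  if (identical(path, system.file("extdata", "gene_synonyms.tsv", package = "tetrimito")))
    .synonym_env$table <- out
  out
}

#' Normalise a gene name
#'
#' @param raw raw gene symbol or product string.
#' @param warn warn when the name is unknown (it is then kept as-is).
#' @return canonical symbol, or the raw name when unknown.
#' @export
normalize_gene_name <- function(raw, warn = TRUE) {
  syn <- gene_synonyms()
  canon <- unique(syn)
  key <- toupper(trimws(raw))
  if (key %in% toupper(canon)) return(canon[match(key, toupper(canon))])
  if (key %in% names(syn)) return(unname(syn[[key]]))
  if (warn) warning("unknown gene symbol kept as-is: ", raw, call. = FALSE)
  raw
}

# ---- FASTA -----------------------------------------------------------------

#' Read a FASTA file
#'
#' Sequences are upper-cased and U mapped to T; non-IUPAC characters are
#' rejected; duplicate identifiers are an error.
#'
#' @param path FASTA file.
#' @return named character vector of sequences, input order preserved.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate FASTA identifiers: ", paste(dup, collapse = ", "))
  seqs <- chartr("U", "T", toupper(as.character(set)))
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1L]])
    bad <- setdiff(chars, strsplit("ACGTNRYKMSWBDHV", "")[[1L]])
    if (length(bad) > 0L)
      stop(sprintf("record '%s' contains non-IUPAC symbol(s): %s",
                   ids[i], paste(bad, collapse = ", ")))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- GenBank flat file -----------------------------------------------------

.GB_KEY_KIND <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                  `D-loop` = "noncoding", misc_feature = "noncoding",
                  rep_origin = "noncoding")
.KIND_GB_KEY <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  noncoding = "misc_feature")

#' @keywords internal
parse_gb_location <- function(loc, L, id) {
  loc <- gsub("[<> ]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  spans <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", p))[[1L]]
    if (length(m) == 0L) stop("unparseable location '", p, "' in ", id)
    a <- as.integer(m[2])
    b <- if (nzchar(m[4])) as.integer(m[4]) else a
    c(a, b)
  })
  for (sp in spans) {
    if (sp[1] > sp[2]) stop("reversed span in location of ", id)
    if (sp[2] > L) stop(sprintf("feature coordinate %d beyond sequence length %d in %s",
                                sp[2], L, id))
  }
  if (length(spans) == 1L) {
    list(start = spans[[1]][1] - 1L, end = spans[[1]][2], wraps = FALSE, strand = strand)
  } else if (length(spans) == 2L && spans[[1]][2] == L && spans[[2]][1] == 1L) {
    list(start = spans[[1]][1] - 1L, end = spans[[2]][2], wraps = TRUE, strand = strand)
  } else {
    stop("unsupported compound location in ", id, ": ", loc)
  }
}

#' Read GenBank flat-file records
#'
#' Parses LOCUS entries into \code{mitogenome_record}s: 1-based inclusive
#' coordinates become 0-based half-open, \code{join()} features spanning the
#' origin become single features with \code{wraps_origin = TRUE}, gene names
#' are normalised through \code{\link{gene_synonyms}} (unknown names kept
#' with a warning), and the feature kind comes from the feature key (CDS,
#' tRNA, rRNA, D-loop/misc_feature).
#'
#' @param path GenBank flat file with one or more LOCUS entries.
#' @return list of \code{mitogenome_record}.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^LOCUS", lines)))
    stop("not a GenBank flat file (no LOCUS line): ", path)
  rec_starts <- grep("^LOCUS", lines)
  rec_ends <- grep("^//\\s*$", lines)
  if (length(rec_ends) < length(rec_starts))
    stop("malformed GenBank file: missing '//' terminator in ", path)
  records <- vector("list", length(rec_starts))
  for (r in seq_along(rec_starts)) {
    block <- lines[rec_starts[r]:rec_ends[r]]
    records[[r]] <- parse_gb_record(block, path)
  }
  records
}

#' @keywords internal
parse_gb_record <- function(block, path) {
  locus <- block[1L]
  m <- regmatches(locus, regexec(
    "^LOCUS\\s+(\\S+)\\s+([0-9]+)\\s+bp\\s+\\S+\\s+(circular|linear)?", locus))[[1L]]
  if (length(m) == 0L || !nzchar(m[2]))
    stop("malformed LOCUS header at line: ", locus)
  id <- m[2]; L <- as.integer(m[3])
  circular <- identical(m[4], "circular")

  org_line <- grep("^\\s+ORGANISM\\s+", block, value = TRUE)
  source_txt <- if (length(org_line) > 0L)
    trimws(sub("^\\s+ORGANISM\\s+", "", org_line[1L])) else ""

  # sequence
  oi <- grep("^ORIGIN", block)
  seq_txt <- ""
  if (length(oi) == 1L) {
    seq_lines <- block[(oi + 1L):(length(block) - 1L)]
    seq_txt <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  if (nchar(seq_txt) != L)
    stop(sprintf("sequence length %d does not match LOCUS length %d for %s",
                 nchar(seq_txt), L, id))

  # features
  fi <- grep("^FEATURES", block)
  feats <- gene_features(character(), character(), integer(), integer())
  if (length(fi) == 1L) {
    fend <- if (length(oi) == 1L) oi - 1L else length(block) - 1L
    flines <- block[(fi + 1L):fend]
    starts <- grep("^ {5}\\S", flines)
    bounds <- c(starts, length(flines) + 1L)
    rows <- list()
    for (i in seq_along(starts)) {
      chunk <- flines[starts[i]:(bounds[i + 1L] - 1L)]
      key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1L])
      if (!key %in% names(.GB_KEY_KIND)) next
      # location may continue over lines until the first qualifier
      body <- sub("^ {5}\\S+\\s*", "", chunk[1L])
      j <- 2L
      while (j <= length(chunk) && !grepl("^\\s*/", chunk[j])) {
        body <- paste0(body, trimws(chunk[j])); j <- j + 1L
      }
      quals <- chunk[grepl("^\\s*/", chunk)]
      getq <- function(q) {
        hit <- grep(paste0("^\\s*/", q, "="), quals, value = TRUE)
        if (length(hit) == 0L) return(NA_character_)
        gsub('^[^=]*=|"', "", hit[1L])
      }
      loc <- parse_gb_location(body, L, id)
      raw <- getq("gene")
      if (is.na(raw)) raw <- getq("product")
      if (is.na(raw)) raw <- getq("note")
      kind <- unname(.GB_KEY_KIND[[key]])
      name <- if (is.na(raw)) {
        if (kind == "noncoding") "control_region" else paste0("unknown_", key)
      } else normalize_gene_name(raw)
      ac <- getq("anticodon")
      if (!is.na(ac)) {
        if (grepl("seq:", ac)) ac <- sub(".*seq:([A-Za-z]{3}).*", "\\1", ac)
        ac <- toupper(chartr("U", "T", ac))
        if (!grepl("^[ACGT]{3}$", ac)) ac <- NA_character_
      }
      rows[[length(rows) + 1L]] <- gene_features(
        name, kind, loc$start, loc$end, loc$strand, loc$wraps, ac)
    }
    if (length(rows) > 0L) feats <- do.call(rbind, rows)
  }
  mitogenome_record(id, seq_txt, feats, circular = circular, source = source_txt)
}

#' Write records to a GenBank flat file
#'
#' Emits one LOCUS entry per record with CDS/tRNA/rRNA/misc_feature keys,
#' canonical \code{/gene} qualifiers and \code{/anticodon} for tRNAs, so
#' that \code{read_genbank(write_genbank(x))} round-trips the feature table
#' exactly.
#'
#' @param records list of \code{mitogenome_record} (or a single record).
#' @param path output file.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "mitogenome_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    L <- nchar(rec$sequence)
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s INV",
                       rec$id, L, if (rec$circular) "circular" else "linear "), con)
    writeLines(sprintf("DEFINITION  %s mitochondrion.",
                       if (nzchar(rec$source)) rec$source else rec$id), con)
    writeLines(sprintf("ACCESSION   %s", rec$id), con)
    writeLines(sprintf("SOURCE      %s", if (nzchar(rec$source)) rec$source else rec$id), con)
    writeLines(sprintf("  ORGANISM  %s", if (nzchar(rec$source)) rec$source else rec$id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", L), con)
    f <- rec$features
    if (nrow(f) > 0L) for (i in seq_len(nrow(f))) {
      gb <- internal_to_gb(f$start[i], f$end[i])
      loc <- if (f$wraps_origin[i]) {
        sprintf("join(%d..%d,1..%d)", gb$start, L, f$end[i])
      } else sprintf("%d..%d", gb$start, gb$end)
      if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      key <- .KIND_GB_KEY[[f$kind[i]]]
      writeLines(sprintf("     %-15s %s", key, loc), con)
      writeLines(sprintf('                     /gene="%s"', f$name[i]), con)
      if (f$kind[i] == "tRNA" && !is.na(f$anticodon[i]))
        writeLines(sprintf('                     /anticodon="%s"', f$anticodon[i]), con)
    }
    writeLines("ORIGIN", con)
    pos <- seq(1L, L, by = 60L)
    for (p in pos) {
      chunk <- substr(rec$sequence, p, min(p + 59L, L))
      groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
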