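# Intergenic-gap scanning and cloverleaf tRNA candidate prediction. This is
# the discovery procedure for tRNA-like insertions in the anomalously long
# tRNA-Ser/nad1 spacer of Tetrigidae mitogenomes: find spacers longer than a
# strict threshold, then exhaustively attempt cloverleaf assembly inside
# them under standard tRNA geometry.

#' Fold parameters for cloverleaf tRNA prediction
#'
#' Geometry bounds follow standard tRNA architecture: 7-bp acceptor stem,
#' 3-4 bp D-stem with a 4-12 nt loop, 4-5 bp anticodon stem with a fixed
#' 7-nt loop (anticodon at loop positions 3-5), 3-23 nt variable region and
#' 4-5 bp T-stem with a 5-9 nt loop. Watson-Crick pairs score +1, GU wobble
#' pairs +0.5, mismatches (at most \code{max_mismatch} per stem) -1, and
#' each nt of deviation from the canonical geometry costs
#' \code{indel_penalty}. The default acceptance threshold of 18 (out of a
#' canonical maximum of 21) keeps the false-positive rate on shuffled
#' AT-rich spacers below a few percent.
#'
#' @param acc_stem acceptor stem length (bp).
#' @param spacer1 nt between acceptor 5' arm and D-stem.
#' @param d_stem,d_loop D-arm stem (bp) and loop (nt) ranges.
#' @param spacer2 nt between D-arm and anticodon stem.
#' @param ac_stem,ac_loop anticodon stem range (bp) and loop length (nt).
#' @param var_region variable-region length range (nt).
#' @param t_stem,t_loop T-arm stem (bp) and loop (nt) ranges.
#' @param tail_nt 3' extension (discriminator + 2 nt) added to the paired
#'   span when reporting candidate length; the canonical synthetic tRNA is
#'   74 nt under this convention.
#' @param max_mismatch maximum mismatches tolerated per stem.
#' @param gu_score,mismatch_penalty,indel_penalty scoring weights.
#' @param threshold minimum score for a reported candidate.
#' @param min_len,max_len candidate length bounds (nt).
#' @return list of fold parameters.
#' @export
trna_fold_params <- function(acc_stem = 7L, spacer1 = 2L,
                             d_stem = 3:4, d_loop = 4:12, spacer2 = 1L,
                             ac_stem = 4:5, ac_loop = 7L, var_region = 3:23,
                             t_stem = 4:5, t_loop = 5:9, tail_nt = 3L,
                             max_mismatch = 1L, gu_score = 0.5,
                             mismatch_penalty = 1, indel_penalty = 0.5,
                             threshold = 18, min_len = 60L, max_len = 95L) {
  list(acc_stem = acc_stem, spacer1 = spacer1, d_stem = d_stem,
       d_loop = d_loop, spacer2 = spacer2, ac_stem = ac_stem,
       ac_loop = ac_loop, var_region = var_region, t_stem = t_stem,
       t_loop = t_loop, tail_nt = tail_nt, max_mismatch = max_mismatch,
       gu_score = gu_score, mismatch_penalty = mismatch_penalty,
       indel_penalty = indel_penalty, threshold = threshold,
       min_len = min_len, max_len = max_len,
       canonical = list(d_stem = 4L, d_loop = 8L, ac_stem = 5L,
                        var_region = 4L, t_stem = 5L, t_loop = 7L))
}

# Pair-score matrices over codes A=1 C=2 G=3 T=4, 5 = N/overflow sentinel.
#' @keywords internal
pair_matrices <- function(params) {
  PV <- matrix(-params$mismatch_penalty, 5L, 5L)
  PV[1L, 4L] <- PV[4L, 1L] <- 1          # A:T
  PV[2L, 3L] <- PV[3L, 2L] <- 1          # C:G
  PV[3L, 4L] <- PV[4L, 3L] <- params$gu_score  # G:T wobble
  MM <- matrix(1L, 5L, 5L)
  MM[cbind(c(1L, 4L, 2L, 3L, 3L, 4L), c(4L, 1L, 3L, 2L, 4L, 3L))] <- 0L
  GU <- matrix(0L, 5L, 5L)
  GU[3L, 4L] <- GU[4L, 3L] <- 1L
  list(PV = PV, MM = MM, GU = GU)
}

#' @keywords internal
stem_eval <- function(iv, idx5, idx3, mats) {
  # idx5/idx3: index matrices (combos x stem length), idx3 already reversed
  a <- matrix(iv[idx5], nrow = nrow(idx5))
  b <- matrix(iv[idx3], nrow = nrow(idx3))
  list(score = rowSums(matrix(mats$PV[cbind(as.vector(a), as.vector(b))], nrow = nrow(a))),
       mism  = rowSums(matrix(mats$MM[cbind(as.vector(a), as.vector(b))], nrow = nrow(a))),
       gu    = rowSums(matrix(mats$GU[cbind(as.vector(a), as.vector(b))], nrow = nrow(a))))
}

#' @keywords internal
scan_trna_one_strand <- function(sequence, params, mats, code) {
  L <- nchar(sequence)
  iv <- seq_to_int(sequence)
  iv[is.na(iv)] <- 5L
  ivp <- c(iv, rep(5L, 120L))  # overflow sentinel padding
  acc <- params$acc_stem
  geom_dev <- function(ds, dl, as_, vr, ts, tl) {
    cn <- params$canonical
    abs(ds - cn$d_stem) + abs(dl - cn$d_loop) + abs(as_ - cn$ac_stem) +
      abs(vr - cn$var_region) + abs(ts - cn$t_stem) + abs(tl - cn$t_loop)
  }
  min_span <- acc + params$spacer1 + 2L * min(params$d_stem) + min(params$d_loop) +
    params$spacer2 + 2L * min(params$ac_stem) + params$ac_loop +
    min(params$var_region) + 2L * min(params$t_stem) + min(params$t_loop) + acc
  if (L < min_span) return(empty_candidates())

  out <- list()
  t_combos <- expand.grid(ts = params$t_stem, tl = params$t_loop)

  for (i in seq_len(L - min_span + 1L)) {
    acc5 <- i:(i + acc - 1L)
    d_start <- i + acc + params$spacer1
    best <- NULL
    # all D-arm geometries per stem length in one vectorised evaluation
    d_surv <- list()
    for (ds in params$d_stem) {
      d5 <- d_start:(d_start + ds - 1L)
      d3s <- d_start + ds + params$d_loop
      ev <- stem_eval(ivp,
                      matrix(rep(d5, each = length(d3s)), nrow = length(d3s)),
                      outer(d3s, (ds - 1L):0L, "+"), mats)
      keep <- which(ev$mism <= params$max_mismatch)
      for (w in keep)
        d_surv[[length(d_surv) + 1L]] <- list(
          ds = ds, dl = params$d_loop[w],
          score = ev$score[w], mism = ev$mism[w], gu = ev$gu[w])
    }
    for (dsv in d_surv) {
      ds <- dsv$ds; dl <- dsv$dl
      ev_d <- list(score = dsv$score, mism = dsv$mism, gu = dsv$gu)
      d3s <- d_start + ds + dl
      ac_start <- d3s + ds + params$spacer2
      for (as_ in params$ac_stem) {
        loop_s <- ac_start + as_
        ev_ac <- stem_eval(ivp, matrix(ac_start:(ac_start + as_ - 1L), 1L),
                           matrix((loop_s + params$ac_loop + as_ - 1L):(loop_s + params$ac_loop), 1L),
                           mats)
        if (ev_ac$mism > params$max_mismatch) next
        ac_end <- loop_s + params$ac_loop + as_  # first position after AC arm
        anticodon_idx <- (loop_s + 2L):(loop_s + 4L)
        for (ti in seq_len(nrow(t_combos))) {
          ts <- t_combos$ts[ti]; tl <- t_combos$tl[ti]
          t_starts <- ac_end + params$var_region
          idxT5 <- outer(t_starts, 0L:(ts - 1L), "+")
          idxT3 <- outer(t_starts + ts + tl, (ts - 1L):0L, "+")
          ev_t <- stem_eval(ivp, idxT5, idxT3, mats)
          acc3s <- t_starts + 2L * ts + tl
          idxA3 <- outer(acc3s, (acc - 1L):0L, "+")
          idxA5 <- matrix(rep(acc5, each = length(t_starts)), nrow = length(t_starts))
          ev_a <- stem_eval(ivp, idxA5, idxA3, mats)
          span <- acc3s + acc - i
          len <- pmin(span + params$tail_nt, L - i + 1L)
          ok <- ev_t$mism <= params$max_mismatch &
            ev_a$mism <= params$max_mismatch &
            (acc3s + acc - 1L) <= L &
            len >= params$min_len & len <= params$max_len
          if (!any(ok)) next
          dev <- geom_dev(ds, dl, as_, params$var_region, ts, tl)
          score <- ev_d$score + ev_ac$score + ev_t$score + ev_a$score -
            params$indel_penalty * dev
          score[!ok] <- -Inf
          j <- which.max(score)
          if (score[j] >= params$threshold &&
              (is.null(best) || score[j] > best$score)) {
            acv <- paste(c("A", "C", "G", "T", "N")[ivp[anticodon_idx]], collapse = "")
            best <- list(
              offset = i - 1L, length = len[j], score = score[j],
              anticodon = acv,
              mismatches = ev_d$mism + ev_ac$mism + ev_t$mism[j] + ev_a$mism[j],
              gu_pairs = ev_d$gu + ev_ac$gu + ev_t$gu[j] + ev_a$gu[j],
              d_stem = ds, d_loop = dl, ac_stem = as_,
              var_len = params$var_region[j], t_stem = ts, t_loop = tl)
          }
        }
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  if (length(out) == 0L) return(empty_candidates())
  do.call(rbind, lapply(out, function(b) {
    data.frame(offset = b$offset, length = b$length, strand = "+",
               score = b$score, anticodon = b$anticodon,
               amino_acid = if (grepl("N", b$anticodon)) NA_character_
                            else decode_anticodon(b$anticodon, code),
               mismatches = b$mismatches, gu_pairs = b$gu_pairs,
               d_stem = b$d_stem, d_loop = b$d_loop, ac_stem = b$ac_stem,
               var_len = b$var_len, t_stem = b$t_stem, t_loop = b$t_loop,
               stringsAsFactors = FALSE)
  }))
}

#' @keywords internal
empty_candidates <- function() {
  data.frame(offset = integer(), length = integer(), strand = character(),
             score = numeric(), anticodon = character(),
             amino_acid = character(), mismatches = integer(),
             gu_pairs = numeric(), d_stem = integer(), d_loop = integer(),
             ac_stem = integer(), var_len = integer(), t_stem = integer(),
             t_loop = integer(), stringsAsFactors = FALSE)
}

#' Predict cloverleaf tRNA candidates in a sequence
#'
#' Exhaustively scans both strands, attempting cloverleaf assembly at every
#' offset under the geometric bounds in \code{params}. Candidates scoring
#' at least \code{params$threshold} are returned best-first; the anticodon
#' (loop positions 3-5, read 5'-3' on the tRNA sense strand) is decoded to
#' an amino acid by reverse-complement lookup in the genetic code. Offsets
#' are 0-based on the forward strand of the input.
#'
#' @param sequence DNA string (a spacer/gap sequence, typically).
#' @param code a \code{\link{genetic_code}}.
#' @param params \code{\link{trna_fold_params}}.
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return data.frame of candidates: \code{offset}, \code{length},
#'   \code{strand}, \code{score}, \code{anticodon}, \code{amino_acid},
#'   \code{mismatches}, \code{gu_pairs} and the arm geometry.
#' @export
predict_trna <- function(sequence, code = genetic_code(5L),
                         params = trna_fold_params(), both_strands = TRUE) {
  sequence <- toupper(sequence)
  assert_dna(sequence, allow_n = TRUE)
  mats <- pair_matrices(params)
  fwd <- scan_trna_one_strand(sequence, params, mats, code)
  if (both_strands) {
    L <- nchar(sequence)
    rev <- scan_trna_one_strand(revcomp(sequence), params, mats, code)
    if (nrow(rev) > 0L) {
      rev$strand <- "-"
      rev$offset <- L - (rev$offset + rev$length)
      fwd <- rbind(fwd, rev)
    }
  }
  if (nrow(fwd) == 0L) return(fwd)
  fwd <- fwd[order(-fwd$score, fwd$offset, fwd$strand), , drop = FALSE]
  rownames(fwd) <- NULL
  fwd
}

#' Dot-bracket secondary-structure string for a tRNA candidate
#'
#' @param candidate one row of a \code{\link{predict_trna}} result.
#' @param params the fold parameters used for prediction.
#' @return character scalar in dot-bracket notation covering the paired
#'   span (tail excluded).
#' @export
trna_structure_string <- function(candidate, params = trna_fold_params()) {
  if (is.data.frame(candidate)) candidate <- as.list(candidate[1L, ])
  with(c(candidate, params), paste0(
    strrep("(", acc_stem), strrep(".", spacer1),
    strrep("(", d_stem), strrep(".", d_loop), strrep(")", d_stem),
    strrep(".", spacer2),
    strrep("(", ac_stem), strrep(".", ac_loop), strrep(")", ac_stem),
    strrep(".", var_len),
    strrep("(", t_stem), strrep(".", t_loop), strrep(")", t_stem),
    strrep(")", acc_stem)))
}

# ---- intergenic gaps -------------------------------------------------------

#' Find intergenic gaps in an annotated mitogenome
#'
#' Features are projected to forward-strand intervals (origin-wrapping
#' features contribute both spans), sorted and merged for spacing purposes;
#' the spacers between consecutive merged blocks -- including the
#' wrap-around spacer on circular records -- are returned when strictly
#' longer than \code{min_length}. The default of 20 nt implements the
#' "exceeding 20 bp" rule for anomalous Tetrigidae spacers; gaps are never
#' computed inside annotated features.
#'
#' @param record a \code{mitogenome_record} with >= 2 features.
#' @param min_length strict lower bound on reported gap length (default 20).
#' @return data.frame: \code{upstream_gene}, \code{downstream_gene},
#'   \code{start}, \code{end} (0-based half-open; \code{wraps} marks
#'   origin-spanning gaps), \code{length}, \code{sequence}.
#' @export
find_intergenic_gaps <- function(record, min_length = 20L) {
  stopifnot(inherits(record, "mitogenome_record"))
  f <- record$features
  if (nrow(f) < 2L) stop("record has fewer than 2 features")
  L <- nchar(record$sequence)
  spans <- do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
    sp <- feature_spans(as.list(f[i, ]), L)
    do.call(rbind, lapply(sp, function(s)
      data.frame(start = s[1], end = s[2], name = f$name[i])))
  }))
  spans <- spans[order(spans$start, -spans$end), , drop = FALSE]
  # merge overlapping/abutting spans, remembering boundary gene names
  merged <- list()
  cur <- spans[1L, ]
  for (i in seq_len(nrow(spans))[-1L]) {
    if (spans$start[i] <= cur$end) {
      if (spans$end[i] > cur$end) { cur$end <- spans$end[i]; cur$name <- spans$name[i] }
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- spans[i, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  m <- do.call(rbind, merged)
  first_names <- vapply(seq_len(nrow(m)), function(i) {
    cand <- spans$name[spans$start >= m$start[i] & spans$start <= m$end[i]]
    cand[1L]
  }, character(1))

  gaps <- list()
  if (nrow(m) >= 2L) for (i in seq_len(nrow(m) - 1L)) {
    gstart <- m$end[i]; gend <- m$start[i + 1L]
    if (gend > gstart) {
      gaps[[length(gaps) + 1L]] <- data.frame(
        upstream_gene = m$name[i], downstream_gene = first_names[i + 1L],
        start = gstart, end = gend, wraps = FALSE, length = gend - gstart,
        stringsAsFactors = FALSE)
    }
  }
  if (record$circular) {
    gstart <- m$end[nrow(m)]; gend <- m$start[1L]
    wrap_len <- (L - gstart) + gend
    if (wrap_len > 0L) {
      # the closing spacer crosses the origin unless it lies wholly on one side
      if (gstart >= L) { gstart <- 0L; wraps <- FALSE }      # gap is [0, gend)
      else if (gend == 0L) { gend <- L; wraps <- FALSE }     # gap is [gstart, L)
      else wraps <- TRUE
      gaps[[length(gaps) + 1L]] <- data.frame(
        upstream_gene = m$name[nrow(m)], downstream_gene = first_names[1L],
        start = gstart, end = gend, wraps = wraps,
        length = wrap_len, stringsAsFactors = FALSE)
    }
  }
  if (length(gaps) == 0L) return(cbind(empty_gaps(), sequence = character()))
  g <- do.call(rbind, gaps)
  g <- g[g$length > min_length, , drop = FALSE]
  if (nrow(g) == 0L) return(cbind(empty_gaps(), sequence = character()))
  g$sequence <- vapply(seq_len(nrow(g)), function(i)
    circular_substr(record$sequence, g$start[i], g$end[i], g$wraps[i]),
    character(1))
  rownames(g) <- NULL
  g
}

#' @keywords internal
empty_gaps <- function() {
  data.frame(upstream_gene = character(), downstream_gene = character(),
             start = integer(), end = integer(), wraps = logical(),
             length = integer(), stringsAsFactors = FALSE)
}

#' Survey a named intergenic gap across species
#'
#' For each record, locates the gap between \code{upstream} and
#' \code{downstream} (names normalised; order-insensitive), runs
#' \code{\link{predict_trna}} on it when longer than \code{min_length}, and
#' reports the best candidate. Records lacking the flanking pair get status
#' \code{"gap absent"}; short gaps \code{"below threshold"}; gaps with no
#' fold \code{"no candidate"}. When at least two hits exist, the pairwise
#' ungapped identity of the candidate sequences (trimmed to the shortest)
#' is attached as attribute \code{"identity"}.
#'
#' @param records list of \code{mitogenome_record}.
#' @param upstream,downstream flanking gene names (e.g. "trnS2", "nad1").
#' @param min_length strict gap-length threshold (default 20).
#' @param code a \code{\link{genetic_code}}.
#' @param params \code{\link{trna_fold_params}}.
#' @return data.frame, one row per record: \code{taxon}, \code{status},
#'   \code{gap_length}, \code{offset}, \code{length}, \code{strand},
#'   \code{anticodon}, \code{amino_acid}, \code{score}.
#' @export
cross_species_gap_survey <- function(records, upstream, downstream,
                                     min_length = 20L,
                                     code = genetic_code(5L),
                                     params = trna_fold_params()) {
  if (inherits(records, "mitogenome_record")) records <- list(records)
  stopifnot(length(records) >= 1L)
  up <- normalize_gene_name(upstream, warn = FALSE)
  dn <- normalize_gene_name(downstream, warn = FALSE)
  rows <- list(); hit_seqs <- character()
  for (rec in records) {
    gaps <- find_intergenic_gaps(rec, min_length = 0L)
    sel <- which((gaps$upstream_gene == up & gaps$downstream_gene == dn) |
                 (gaps$upstream_gene == dn & gaps$downstream_gene == up))
    row <- data.frame(taxon = rec$id, status = "gap absent",
                      gap_length = NA_integer_, offset = NA_integer_,
                      length = NA_integer_, strand = NA_character_,
                      anticodon = NA_character_, amino_acid = NA_character_,
                      score = NA_real_, stringsAsFactors = FALSE)
    if (length(sel) > 0L) {
      gap <- gaps[sel[1L], ]
      row$gap_length <- gap$length
      if (gap$length <= min_length) {
        row$status <- "below threshold"
      } else {
        cands <- predict_trna(gap$sequence, code, params)
        if (nrow(cands) == 0L) {
          row$status <- "no candidate"
        } else {
          b <- cands[1L, ]
          row$status <- "hit"
          row$offset <- b$offset; row$length <- b$length
          row$strand <- b$strand; row$anticodon <- b$anticodon
          row$amino_acid <- b$amino_acid; row$score <- b$score
          cand_seq <- substr(gap$sequence, b$offset + 1L, b$offset + b$length)
          if (b$strand == "-") cand_seq <- revcomp(cand_seq)
          hit_seqs[rec$id] <- cand_seq
        }
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(hit_seqs) >= 2L) {
    n <- length(hit_seqs)
    trim <- min(nchar(hit_seqs))
    idm <- matrix(1, n, n, dimnames = list(names(hit_seqs), names(hit_seqs)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      a <- strsplit(substr(hit_seqs[i], 1L, trim), "")[[1L]]
      b <- strsplit(substr(hit_seqs[j], 1L, trim), "")[[1L]]
      idm[i, j] <- idm[j, i] <- mean(a == b)
    }
    attr(out, "identity") <- idm
  }
  out
}
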