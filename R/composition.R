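# Nucleotide composition, AT/GC skews, and sliding-window content profiles.
# Percentages are always over unambiguous bases; Ns are counted but excluded
# from every denominator.

#' Base composition of a DNA sequence
#'
#' Insect mitogenomes are strongly AT-rich (Tetrigidae exceed 70\% AT, with
#' A the modal base and G the rarest); this function reports the counts,
#' percentages and strand skews used to describe that bias. Skews follow
#' the usual conventions AT-skew = (A-T)/(A+T) and GC-skew = (G-C)/(G+C);
#' a zero denominator yields NA, not 0.
#'
#' @param sequence DNA string over A/C/G/T/N (or a \code{mitogenome_record}).
#' @return list of class \code{composition_stats}: per-base \code{counts},
#'   per-base \code{pct}, \code{at_pct}, \code{gc_pct}, \code{at_skew},
#'   \code{gc_skew}, \code{n_excluded}.
#' @export
#' @examples
#' base_composition("AAAT")$at_skew  # 0.5
base_composition <- function(sequence) {
  if (inherits(sequence, "mitogenome_record")) sequence <- sequence$sequence
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  sequence <- toupper(sequence)
  assert_dna(sequence, allow_n = TRUE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  counts <- vapply(c(DNA_BASES, "N"), function(b) sum(chars == b), integer(1))
  n_unamb <- sum(counts[DNA_BASES])
  if (n_unamb == 0L) stop("no unambiguous bases in sequence")
  pct <- 100 * counts[DNA_BASES] / n_unamb
  a <- counts[["A"]]; c_ <- counts[["C"]]; g <- counts[["G"]]; t <- counts[["T"]]
  structure(list(
    counts = counts[DNA_BASES],
    pct = pct,
    at_pct = unname(pct[["A"]] + pct[["T"]]),
    gc_pct = unname(pct[["G"]] + pct[["C"]]),
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_,
    n_excluded = unname(counts[["N"]])
  ), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("AT%% %.2f GC%% %.2f | AT-skew %s GC-skew %s | A %d C %d G %d T %d (N %d)\n",
              x$at_pct, x$gc_pct,
              formatC(x$at_skew, digits = 3, format = "f"),
              formatC(x$gc_skew, digits = 3, format = "f"),
              x$counts[["A"]], x$counts[["C"]], x$counts[["G"]], x$counts[["T"]],
              x$n_excluded))
  invisible(x)
}

#' Sliding-window AT/GC content profile
#'
#' Windows of \code{window_size} nucleotides advance by \code{step}; on a
#' circular record windows wrap the origin, giving \code{ceiling(L/step)}
#' windows anchored at the record's position 0. The 100-nt default matches
#' the window used for circular mitogenome content plots.
#'
#' @param x a \code{mitogenome_record} or DNA string.
#' @param window_size window length in nt (default 100).
#' @param step advance in nt (default = \code{window_size}, non-overlapping).
#' @param circular override circularity (defaults to the record's flag;
#'   FALSE for a bare string).
#' @return data.frame with columns \code{start} (0-based), \code{at_pct},
#'   \code{gc_pct}; attribute \code{window_size}, \code{step}, \code{circular}.
#' @export
sliding_window_profile <- function(x, window_size = 100L, step = window_size,
                                   circular = NULL) {
  stopifnot(window_size >= 1L, step >= 1L)
  if (inherits(x, "mitogenome_record")) {
    if (is.null(circular)) circular <- x$circular
    s <- x$sequence
  } else {
    if (is.null(circular)) circular <- FALSE
    s <- toupper(x)
  }
  L <- nchar(s)
  if (!circular && window_size > L)
    stop("window_size exceeds sequence length on a linear record")
  starts <- if (circular) seq(0L, L - 1L, by = step)
            else seq(0L, L - window_size, by = step)
  vals <- vapply(starts, function(st) {
    en <- st + window_size
    w <- if (en <= L) substr(s, st + 1L, en)
         else paste0(substr(s, st + 1L, L), substr(s, 1L, en - L))
    comp <- base_composition(w)
    c(comp$at_pct, comp$gc_pct)
  }, numeric(2))
  out <- data.frame(start = starts, at_pct = vals[1L, ], gc_pct = vals[2L, ])
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  attr(out, "circular") <- circular
  out
}
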