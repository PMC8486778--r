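#' Assign GC fractions to genome windows
#'
#' GC content can come from genome sequence or from a precomputed track;
#' both paths fill the same `gc` field. From sequence, gc is
#' (G+C)/(A+C+G+T) over the window with ambiguous bases excluded from the
#' denominator; an all-N window gets `NA` and is flagged unusable. From a
#' bedGraph track, the window GC is the coverage-weighted mean of the
#' track values overlapping the window.
#'
#' @param windows A `genomic_windows` data frame.
#' @param sequence A named [Biostrings::DNAStringSet] covering the
#'   windows' chromosomes.
#' @param gc Numeric vector of per-window GC fractions, parallel to
#'   `windows`.
#' @param gc_track `data.frame` as returned by [read_bedgraph()].
#' @return `windows` with the `gc` column filled.
#' @export
window_gc <- function(windows, sequence = NULL, gc = NULL, gc_track = NULL) {
  n_src <- sum(!is.null(sequence), !is.null(gc), !is.null(gc_track))
  if (n_src != 1)
    stop("supply exactly one of 'sequence', 'gc', 'gc_track'")
  if (!is.null(gc)) {
    if (length(gc) != nrow(windows))
      stop("'gc' must have one value per window")
    if (any(gc < 0 | gc > 1, na.rm = TRUE))
      stop("GC fractions must be in [0, 1]")
    windows$gc <- as.numeric(gc)
    return(windows)
  }
  if (!is.null(sequence)) {
    missing_chr <- setdiff(unique(windows$chrom), names(sequence))
    if (length(missing_chr))
      stop("sequence missing for: ", paste(missing_chr, collapse = ", "))
    windows$gc <- vapply(seq_len(nrow(windows)), function(i) {
      sq <- Biostrings::subseq(sequence[[windows$chrom[i]]],
                               start = windows$start[i] + 1,
                               end = windows$end[i])
      counts <- Biostrings::letterFrequency(sq, c("A", "C", "G", "T"))
      denom <- sum(counts)
      if (denom == 0) return(NA_real_)
      unname((counts[["C"]] + counts[["G"]]) / denom)
    }, numeric(1))
    return(windows)
  }
  # bedGraph path: overlap-length weighted mean of track values
  wgr <- .as_granges(windows)
  tgr <- .as_granges(gc_track)
  hits <- GenomicRanges::findOverlaps(wgr, tgr)
  ov <- IRanges::width(IRanges::pintersect(
    wgr[S4Vectors::queryHits(hits)], tgr[S4Vectors::subjectHits(hits)]))
  num <- rep(0, nrow(windows))
  den <- rep(0, nrow(windows))
  q <- S4Vectors::queryHits(hits)
  val <- gc_track$value[S4Vectors::subjectHits(hits)]
  num <- num + as.numeric(tapply(ov * val, factor(q, seq_len(nrow(windows))),
                                 sum, default = 0))
  den <- den + as.numeric(tapply(ov, factor(q, seq_len(nrow(windows))),
                                 sum, default = 0))
  windows$gc <- ifelse(den > 0, num / den, NA_real_)
  windows
}

#' Subtract peak base pairs from window lengths
#'
#' Off-target coverage is measured outside called peaks, so each
#' window's denominator is its effective length: total length minus the
#' base pairs covered by (merged) peaks. Windows left with zero
#' effective length are unusable.
#'
#' @param windows A `genomic_windows` data frame.
#' @param peaks Peak regions (`chrom`, `start`, `end`); overlapping peaks
#'   are merged before subtraction.
#' @return `windows` with `effective_length` updated.
#' @export
effective_window_size <- function(windows, peaks) {
  windows$effective_length <- windows$end - windows$start
  peaks <- .merge_regions(peaks)
  if (nrow(peaks) == 0) return(windows)
  wgr <- .as_granges(windows)
  pgr <- .as_granges(peaks)
  hits <- GenomicRanges::findOverlaps(wgr, pgr)
  if (length(hits)) {
    ov <- IRanges::width(IRanges::pintersect(
      wgr[S4Vectors::queryHits(hits)], pgr[S4Vectors::subjectHits(hits)]))
    covered <- tapply(ov, factor(S4Vectors::queryHits(hits),
                                 seq_len(nrow(windows))), sum, default = 0)
    windows$effective_length <- windows$effective_length - as.numeric(covered)
  }
  if (any(windows$effective_length < 0))
    stop("internal error: negative effective length")
  windows
}
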