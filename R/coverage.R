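#' Off-target window coverage
#'
#' Computes the normalized off-target coverage of every entity (cell or
#' pooled group of cells) in every genome window. Fragments overlapping
#' any peak by at least one bp are excluded, remaining fragments are
#' assigned to the window containing their midpoint, counts are
#' count-column weighted (or collapsed to one per record), divided by the
#' window's effective length to give a per-bp rate, and finally divided
#' by the entity's mean rate over usable autosomal windows so each entity
#' has mean coverage 1 and sequencing depth cancels.
#'
#' @param fragments Fragments `data.frame` (chrom, start, end, barcode,
#'   count); cells should already have passed QC.
#' @param windows `genomic_windows` with `gc` and `effective_length` set.
#' @param peaks Peak regions to exclude (merged internally); `NULL` for
#'   none.
#' @param grouping `NULL` for per-cell profiles (entity = barcode), or a
#'   named character vector mapping barcode to entity for pseudobulk
#'   profiles. Barcodes absent from the map are dropped.
#' @param collapse_duplicates If `TRUE`, ignore the count column and
#'   weight every record once.
#' @param exclude_chroms Chromosomes excluded from the normalization
#'   baseline (default sex chromosomes, whose ploidy is ambiguous).
#' @return Numeric matrix (entities x windows, window-id column names) of
#'   normalized coverage; unusable windows are `NA`. Entities with zero
#'   off-target fragments get all-`NA` rows and a warning.
#' @export
window_coverage <- function(fragments, windows, peaks = NULL,
                            grouping = NULL, collapse_duplicates = FALSE,
                            exclude_chroms = .sex_chroms) {
  usable <- .usable_windows(windows)
  if (!any(usable)) stop("no usable windows")
  if (!is.null(peaks)) {
    peaks <- .merge_regions(peaks)
    if (nrow(peaks)) {
      fgr <- .as_granges(fragments)
      on_target <- IRanges::overlapsAny(fgr, .as_granges(peaks))
      fragments <- fragments[!on_target, , drop = FALSE]
    }
  }
  if (is.null(grouping)) {
    entity <- fragments$barcode
    entities <- sort(unique(entity))
  } else {
    if (is.null(names(grouping))) stop("'grouping' must be named by barcode")
    keep <- fragments$barcode %in% names(grouping)
    fragments <- fragments[keep, , drop = FALSE]
    entity <- unname(grouping[fragments$barcode])
    entities <- sort(unique(unname(grouping)))
  }
  if (nrow(fragments) == 0) stop("no off-target fragments left")
  widx <- .assign_windows(fragments, windows)
  ok <- !is.na(widx)
  w <- if (collapse_duplicates) rep(1, nrow(fragments)) else fragments$count
  counts <- Matrix::sparseMatrix(
    i = match(entity[ok], entities),
    j = widx[ok],
    x = w[ok],
    dims = c(length(entities), nrow(windows)))
  counts <- as.matrix(counts)
  dimnames(counts) <- list(entities, window_id(windows))
  rate <- sweep(counts, 2, windows$effective_length, "/")
  rate[, !usable] <- NA_real_
  baseline <- usable & !(windows$chrom %in% exclude_chroms)
  if (!any(baseline)) stop("no usable autosomal windows for normalization")
  libfactor <- rowMeans(rate[, baseline, drop = FALSE], na.rm = TRUE)
  empty <- !is.finite(libfactor) | libfactor == 0
  if (any(empty)) {
    warning(sum(empty), " entit(ies) with zero off-target coverage ",
            "flagged missing")
    libfactor[empty] <- NA_real_
  }
  rate / libfactor
}

# Midpoint-in-window assignment: returns the row index in `windows`
# holding each fragment's midpoint, NA when outside every window.
.assign_windows <- function(fragments, windows) {
  mid <- floor((fragments$start + fragments$end) / 2)
  widx <- rep(NA_integer_, nrow(fragments))
  for (ch in unique(windows$chrom)) {
    wrows <- which(windows$chrom == ch)
    frows <- which(fragments$chrom == ch)
    if (!length(frows)) next
    pos <- findInterval(mid[frows], windows$start[wrows])
    inside <- pos >= 1 & mid[frows] < windows$end[wrows][pmax(pos, 1)]
    widx[frows[inside]] <- wrows[pos[inside]]
  }
  widx
}

#' GC-matched background windows
#'
#' For every usable window, selects the `n_match` other usable windows
#' with the smallest absolute GC difference; their mean coverage is the
#' amplification-bias-matched background the window is compared to. Ties
#' in |dGC| are broken by genomic order (chrom, start). When fewer than
#' `n_match` candidates exist, all of them are used with a warning.
#'
#' @param windows `genomic_windows` with `gc` assigned.
#' @param n_match Number of matched windows (default 100).
#' @return List (length `nrow(windows)`) of integer index vectors into
#'   `windows`; `NULL` for unusable windows.
#' @export
gc_matched_background <- function(windows, n_match = 100) {
  usable <- which(.usable_windows(windows))
  if (length(usable) < 2) stop("need at least 2 usable windows")
  if (length(usable) - 1 < n_match)
    warning("fewer than n_match = ", n_match,
            " candidate windows; using all ", length(usable) - 1)
  gcs <- windows$gc[usable]
  # genomic order tie-break: `usable` is already in (chrom, start) order
  genomic_rank <- seq_along(usable)
  out <- vector("list", nrow(windows))
  k <- min(n_match, length(usable) - 1)
  for (qi in seq_along(usable)) {
    d <- abs(gcs - gcs[qi])
    d[qi] <- Inf # never match a window to itself
    ord <- order(d, genomic_rank)[seq_len(k)]
    out[[usable[qi]]] <- usable[ord]
  }
  out
}

#' CNV log2 fold change against GC-matched background
#'
#' For each entity and usable window, the log2 ratio of the window's
#' normalized coverage to the mean normalized coverage of its GC-matched
#' background windows, with a pseudocount guarding empty windows.
#'
#' @param coverage Matrix from [window_coverage()].
#' @param background List from [gc_matched_background()].
#' @param eps Pseudocount added to both numerator and denominator
#'   (default 0.01, bounding the log2 fold change of an empty window at
#'   about -6.6 instead of -Inf).
#' @return Matrix of log2 fold changes, same shape as `coverage`;
#'   unusable windows are `NA`.
#' @export
cnv_fold_change <- function(coverage, background, eps = 0.01) {
  if (length(background) != ncol(coverage))
    stop("background list is not aligned to coverage columns")
  lfc <- matrix(NA_real_, nrow(coverage), ncol(coverage),
                dimnames = dimnames(coverage))
  for (w in seq_len(ncol(coverage))) {
    idx <- background[[w]]
    if (is.null(idx)) next
    bg <- rowMeans(coverage[, idx, drop = FALSE])
    lfc[, w] <- log2((coverage[, w] + eps) / (bg + eps))
  }
  lfc
}

#' Pairwise Pearson correlation of CNV profiles
#'
#' @param profiles Matrix of log2 fold changes, entities in rows.
#' @param min_shared Minimum pairwise-complete windows for a defined
#'   entry (default 3).
#' @return Symmetric correlation matrix with unit diagonal; pairs with
#'   too few shared windows are `NA`.
#' @export
correlate_profiles <- function(profiles, min_shared = 3) {
  if (nrow(profiles) < 2) stop("need at least 2 profiles")
  r <- stats::cor(t(profiles), use = "pairwise.complete.obs")
  shared <- crossprod(t(!is.na(profiles)) * 1)
  r[shared < min_shared] <- NA_real_
  diag(r) <- 1
  r
}

#' Mean log2 fold change over a locus
#'
#' Length-weighted mean of window log2 fold changes over the windows a
#' locus overlaps (used e.g. to read out the copy-number status of a
#' single gene such as RB1 from a profile).
#'
#' @param lfc Numeric vector of per-window log2 fold changes.
#' @param windows `genomic_windows` the vector is aligned to.
#' @param locus List or one-row data.frame with `chrom`, `start`, `end`.
#' @return Weighted mean log2 fold change, or `NA` if the locus overlaps
#'   no usable window.
#' @export
locus_cn <- function(lfc, windows, locus) {
  ov <- pmax(0, pmin(windows$end, locus$end) -
                  pmax(windows$start, locus$start))
  ov[windows$chrom != locus$chrom] <- 0
  ok <- ov > 0 & !is.na(lfc)
  if (!any(ok)) return(NA_real_)
  sum(lfc[ok] * ov[ok]) / sum(ov[ok])
}
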