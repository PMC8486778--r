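#' Segment a CNV profile into constant-copy regions
#'
#' Exact penalized least-squares changepoint detection, per chromosome:
#' the partition minimizing within-segment squared error plus a penalty
#' per changepoint is found by dynamic programming (optimal
#' partitioning). The default penalty is `3 * sigma^2 * log(n)` per
#' chromosome, with the noise scale `sigma` estimated robustly from the
#' median absolute successive difference of the profile, pooled over
#' chromosomes. Windows with missing values are dropped before
#' segmentation; chromosomes with fewer than three informative windows
#' form a single segment.
#'
#' @param lfc Numeric vector of per-window log2 fold changes.
#' @param windows `genomic_windows` the vector is aligned to.
#' @param penalty Penalty per changepoint; `NULL` for the default above.
#' @return `data.frame` with one row per segment: `chrom`, `start`,
#'   `end` (bp of the first/last informative window), `first_window`,
#'   `last_window` (row indices into `windows`), `n_windows`,
#'   `mean_log2fc`.
#' @export
segment_profile <- function(lfc, windows, penalty = NULL) {
  stopifnot(length(lfc) == nrow(windows))
  chroms <- unique(windows$chrom)
  if (is.null(penalty)) {
    diffs <- unlist(lapply(chroms, function(ch) {
      x <- lfc[windows$chrom == ch]
      diff(x[!is.na(x)])
    }))
    sigma <- if (length(diffs)) {
      stats::median(abs(diffs)) / (sqrt(2) * stats::qnorm(0.75))
    } else 0
  }
  segs <- lapply(chroms, function(ch) {
    rows <- which(windows$chrom == ch)
    keep <- rows[!is.na(lfc[rows])]
    if (!length(keep)) return(NULL)
    x <- lfc[keep]
    n <- length(x)
    pen <- if (!is.null(penalty)) penalty else
      max(3 * sigma^2 * log(max(n, 2)), 1e-12)
    bp <- if (n < 3) integer(0) else .op_changepoints(x, pen)
    bounds <- cbind(c(1, bp + 1), c(bp, n))
    data.frame(
      chrom = ch,
      start = windows$start[keep[bounds[, 1]]],
      end = windows$end[keep[bounds[, 2]]],
      first_window = keep[bounds[, 1]],
      last_window = keep[bounds[, 2]],
      n_windows = bounds[, 2] - bounds[, 1] + 1L,
      mean_log2fc = vapply(seq_len(nrow(bounds)), function(i)
        mean(x[bounds[i, 1]:bounds[i, 2]]), numeric(1)))
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# Optimal partitioning: minimize sum of within-segment SSE + pen per
# changepoint. O(n^2) with a vectorized inner scan; n is the number of
# windows on one chromosome, so this is desk-scale.
.op_changepoints <- function(x, pen) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  F <- numeric(n + 1)
  F[1] <- -pen
  cp <- integer(n)
  for (t in seq_len(n)) {
    s <- 0:(t - 1)
    len <- t - s
    sse <- (cs2[t + 1] - cs2[s + 1]) - (cs[t + 1] - cs[s + 1])^2 / len
    v <- F[s + 1] + pen + sse
    arg <- which.min(v)
    F[t + 1] <- v[arg]
    cp[t] <- s[arg]
  }
  bp <- integer(0)
  t <- n
  while (t > 0) {
    s <- cp[t]
    if (s > 0) bp <- c(s, bp)
    t <- s
  }
  bp
}

#' Segment many profiles
#'
#' @param profiles Matrix of log2 fold changes, entities in rows.
#' @inheritParams segment_profile
#' @return `data.frame` of segments with a leading `entity` column.
#' @export
segment_profiles <- function(profiles, windows, penalty = NULL) {
  out <- lapply(rownames(profiles), function(e) {
    s <- segment_profile(profiles[e, ], windows, penalty)
    if (is.null(s) || nrow(s) == 0) return(NULL)
    cbind(entity = e, s)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
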