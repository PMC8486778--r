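#' Cluster cells into genetic clones by K-means on CNV profiles
#'
#' K-means on per-cell log2 fold-change vectors (missing windows imputed
#' to 0, sex chromosomes dropped by default), with a fixed seed and the
#' best of `restarts` random starts by total within-cluster sum of
#' squares. Per-window values are winsorized to `[-clip, clip]` first:
#' at single-cell depth a window with a handful of fragments can reach
#' log2 ratios near the pseudocount floor (about -6.6), and without
#' bounding, a single such cell dominates the Euclidean geometry and
#' K-means spends a cluster isolating it instead of separating clones.
#' Ratios beyond ~1.5 log2 units per window carry no additional clonal
#' information, so clipping preserves gain/loss contrasts. Cluster
#' labels are made deterministic by relabeling clusters in increasing
#' order of their center's mean absolute log2 fold change, so label 1
#' is always the flattest, "normal-like" clone.
#'
#' @param profiles Matrix of per-cell log2 fold changes (cells x
#'   windows), typically computed on 2 Mb bins.
#' @param k Number of clones (default 3).
#' @param seed Random seed recorded in the output.
#' @param restarts Number of K-means restarts (default 25).
#' @param clip Winsorization bound on |log2FC| (default 1.5); `Inf`
#'   disables it.
#' @param windows Optional `genomic_windows` aligned to the columns,
#'   needed to honour `exclude_chroms`.
#' @param exclude_chroms Chromosomes dropped before clustering.
#' @return `data.frame` with columns `barcode` and `genetic_label`
#'   (integer 1..k); attributes `seed` and `centers`.
#' @export
cluster_cells_by_cnv <- function(profiles, k = 3, seed = 1, restarts = 25,
                                 clip = 1.5, windows = NULL,
                                 exclude_chroms = .sex_chroms) {
  if (nrow(profiles) < k)
    stop("fewer cells (", nrow(profiles), ") than clusters (", k, ")")
  x <- profiles
  if (!is.null(windows)) {
    stopifnot(ncol(x) == nrow(windows))
    x <- x[, !(windows$chrom %in% exclude_chroms), drop = FALSE]
  }
  x[is.na(x)] <- 0
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100)
  flatness <- rowMeans(abs(km$centers))
  relabel <- match(seq_len(k), order(flatness))
  labels <- relabel[km$cluster]
  out <- data.frame(barcode = rownames(profiles),
                    genetic_label = labels,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "centers") <- km$centers[order(flatness), , drop = FALSE]
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table.
#'
#' @param x,y Label vectors of equal length (any atomic type).
#' @return ARI in \[-1, 1\]; 1 for identical partitions, about 0 for
#'   independent ones.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stop("label vectors differ in length")
  tab <- table(x, y)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  a <- sum_comb(tab)
  b <- sum_comb(rowSums(tab))
  c_ <- sum_comb(colSums(tab))
  expected <- b * c_ / choose(n, 2)
  max_index <- (b + c_) / 2
  if (max_index == expected) return(0)
  (a - expected) / (max_index - expected)
}
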