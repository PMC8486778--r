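#' Two-group differential test on a count matrix
#'
#' A deliberately simple differential test for peak-count or gene-count
#' matrices: counts are library-size normalized (scaled to the mean
#' library size), log2(x + 1) transformed, and compared between groups
#' with a two-sample Welch t-test; p-values are Benjamini-Hochberg
#' adjusted across features. The log2 fold change is the difference of
#' group means on the transformed scale (second group minus `ref`).
#' Features with zero variance in both groups get p = 1.
#'
#' @param counts Non-negative count matrix, features x samples.
#' @param groups Factor (or coercible) of length `ncol(counts)` with
#'   exactly two levels, at least two samples each.
#' @param ref Reference group level (default: first level); positive
#'   log2 fold changes mean higher in the non-reference group.
#' @return `data.frame` with `feature`, `log2_fold_change`, `p_value`,
#'   `adjusted_p`.
#' @export
differential_test <- function(counts, groups, ref = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("'groups' must have exactly 2 levels")
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  if (is.null(ref)) ref <- levels(groups)[1]
  other <- setdiff(levels(groups), ref)
  libsize <- colSums(counts)
  norm <- sweep(counts, 2, libsize / mean(libsize), "/")
  L <- log2(norm + 1)
  i1 <- which(groups == ref)
  i2 <- which(groups == other)
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(L[, i1, drop = FALSE])
  m2 <- rowMeans(L[, i2, drop = FALSE])
  v1 <- apply(L[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(L[, i2, drop = FALSE], 1, stats::var)
  lfc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- 1
  p[!is.finite(p)] <- 1
  p <- pmax(p, .Machine$double.xmin) # keep p in (0, 1]
  data.frame(feature = rownames(counts),
             log2_fold_change = lfc,
             p_value = p,
             adjusted_p = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select differential regions at the study thresholds
#'
#' Two threshold modes: `"ne_vs_ad"` keeps regions gained in the
#' neuroendocrine state (adjusted p < 0.001 and log2FC > 2);
#' `"subtype"` keeps subtype-specific regions (adjusted p < 0.01 and
#' |log2FC| > 1), split by fold-change sign into the two subtype sets.
#'
#' @param results `data.frame` from [differential_test()].
#' @param mode `"ne_vs_ad"` or `"subtype"`.
#' @return For `"ne_vs_ad"`, a character vector of kept features; for
#'   `"subtype"`, a list with `up` and `down` character vectors.
#' @export
apply_region_thresholds <- function(results, mode = c("ne_vs_ad",
                                                      "subtype")) {
  mode <- match.arg(mode)
  if (mode == "ne_vs_ad") {
    keep <- results$adjusted_p < 0.001 & results$log2_fold_change > 2
    return(results$feature[keep])
  }
  sig <- results$adjusted_p < 0.01 & abs(results$log2_fold_change) > 1
  list(up = results$feature[sig & results$log2_fold_change > 0],
       down = results$feature[sig & results$log2_fold_change < 0])
}

#' Link peak summits to the nearest transcription start site
#'
#' Each summit is associated with its nearest TSS when the distance is
#' at most `max_dist` (the +/-50 kb rule); more distant summits stay
#' unmapped. Distance ties are broken by the lexicographically smaller
#' gene identifier.
#'
#' @param summits `data.frame` with `chrom`, `pos` and optionally
#'   `name`.
#' @param tss `data.frame` with unique `gene`, `chrom`, `tss` (the
#'   strand-aware TSS position in bp).
#' @param max_dist Maximum linking distance in bp (default 50000).
#' @return `data.frame` with `summit`, `gene` (`NA` when unmapped) and
#'   `distance`.
#' @export
link_peaks_to_genes <- function(summits, tss, max_dist = 50000) {
  if (anyDuplicated(tss$gene)) stop("TSS table has duplicate gene ids")
  nm <- if (!is.null(summits$name)) summits$name
        else as.character(seq_len(nrow(summits)))
  gene <- rep(NA_character_, nrow(summits))
  dist <- rep(NA_real_, nrow(summits))
  for (i in seq_len(nrow(summits))) {
    cand <- tss[tss$chrom == summits$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    d <- abs(cand$tss - summits$pos[i])
    best <- min(d)
    if (best > max_dist) next
    hit <- cand$gene[d == best]
    gene[i] <- sort(hit)[1]
    dist[i] <- best
  }
  data.frame(summit = nm, gene = gene, distance = dist,
             stringsAsFactors = FALSE)
}

#' Build a transcription-factor subtype signature
#'
#' Ranks upregulated genes by `log2FC x (-log10 p)` and keeps the top
#' `n` (the construction used for the ASCL1/NEUROD1 subtype signatures:
#' 50 genes near subtype-specific accessible peaks). Ties are broken by
#' gene identifier so the signature is deterministic given the
#' differential table.
#'
#' @param results Gene-level `data.frame` from [differential_test()]
#'   oriented so that positive fold change means up in the subtype.
#' @param genes Optional character vector restricting eligibility (e.g.
#'   genes with a linked subtype-specific peak within 50 kb).
#' @param n Signature size (default 50); fewer eligible genes trigger a
#'   warning and a shorter signature.
#' @param name Signature name.
#' @return A `signature_set` list with `name`, `genes` (ordered), and
#'   `scores`.
#' @export
build_signature <- function(results, genes = NULL, n = 50,
                            name = "signature") {
  if (!is.null(genes))
    results <- results[results$feature %in% genes, , drop = FALSE]
  up <- results[results$log2_fold_change > 0, , drop = FALSE]
  score <- up$log2_fold_change * (-log10(up$p_value))
  ord <- order(-score, up$feature)
  if (nrow(up) < n)
    warning("only ", nrow(up), " eligible upregulated genes (< ", n, ")")
  take <- utils::head(ord, n)
  structure(list(name = name, genes = up$feature[take],
                 scores = score[take]),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set '", x$name, "': ", length(x$genes), " genes\n",
      sep = "")
  invisible(x)
}
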