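#' Single-sample KS enrichment score
#'
#' The signed Kolmogorov-Smirnov rank statistic used for single-sample
#' gene-set scoring: per sample, genes are ranked by expression
#' (descending; the order among exact ties is fixed by gene id), and a
#' running sum is walked down the ranking, incremented by 1/|S| at
#' signature genes and decremented by 1/(N - |S|) elsewhere. The score
#' is the maximum deviation of the running sum from zero, signed by its
#' direction, so it lies in \[-1, 1\]: +1 when the signature occupies the
#' top |S| ranks, -1 when it occupies the bottom. The score depends only
#' on ranks, hence is invariant to any strictly monotone transform of a
#' sample's expression values.
#'
#' @param expr Expression matrix, genes x samples.
#' @param signature A `signature_set` or character vector of gene ids;
#'   genes absent from the matrix are dropped with a warning.
#' @return Named numeric vector of per-sample scores (`NA` if no
#'   signature gene survives).
#' @export
ks_enrichment <- function(expr, signature) {
  genes <- if (inherits(signature, "signature_set")) signature$genes
           else as.character(signature)
  present <- intersect(genes, rownames(expr))
  if (length(present) < length(genes))
    warning(length(genes) - length(present),
            " signature gene(s) absent from the matrix; dropped")
  N <- nrow(expr)
  m <- length(present)
  scores <- rep(NA_real_, ncol(expr))
  names(scores) <- colnames(expr)
  if (m == 0 || m >= N) {
    if (m >= N) warning("signature covers the whole matrix; score undefined")
    return(scores)
  }
  is_hit <- rownames(expr) %in% present
  rn <- rownames(expr)
  step_hit <- 1 / m
  step_miss <- 1 / (N - m)
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], rn)
    rs <- cumsum(ifelse(is_hit[ord], step_hit, -step_miss))
    scores[j] <- rs[which.max(abs(rs))]
  }
  scores
}

#' Difference of the two subtype scores
#'
#' `delta = score(ASCL1 signature) - score(NEUROD1 signature)` per
#' sample; antisymmetric under exchanging the two signatures. Missing
#' inputs propagate.
#'
#' @param score_a,score_b Per-sample score vectors (aligned).
#' @return Numeric vector of deltas.
#' @export
subtype_delta <- function(score_a, score_b) {
  if (length(score_a) != length(score_b))
    stop("score vectors differ in length")
  score_a - score_b
}

#' Normalized ASCL1/NEUROD1 expression ratio
#'
#' The per-sample ratio of the two marker expressions (with a
#' pseudocount guarding zero denominators, e.g. samples with essentially
#' absent NEUROD1), standardized across the cohort by subtracting the
#' mean and dividing by the SD.
#'
#' @param expr Expression matrix, genes x samples.
#' @param numerator,denominator Marker gene ids (defaults ASCL1,
#'   NEUROD1).
#' @param pseudocount Added to both expressions before the ratio
#'   (default 1).
#' @return Named numeric vector of z-scores (mean 0, SD 1 over the
#'   cohort).
#' @export
normalized_tf_ratio <- function(expr, numerator = "ASCL1",
                                denominator = "NEUROD1",
                                pseudocount = 1) {
  for (g in c(numerator, denominator))
    if (!g %in% rownames(expr)) stop("gene not in matrix: ", g)
  if (ncol(expr) < 2)
    stop("need at least 2 samples to standardize the ratio")
  ratio <- (expr[numerator, ] + pseudocount) /
    (expr[denominator, ] + pseudocount)
  s <- stats::sd(ratio)
  if (s == 0) {
    warning("ratio has zero variance; all z set to 0")
    return(stats::setNames(rep(0, length(ratio)), colnames(expr)))
  }
  (ratio - mean(ratio)) / s
}

#' Rank association between score difference and marker ratio
#'
#' Spearman rank correlation (average ranks for ties) between the
#' signature score delta and the normalized marker ratio, with the
#' p-value from the t approximation.
#'
#' @param delta,z Paired numeric vectors; pairs with missing values are
#'   dropped.
#' @return List with `rho`, `p`, `n`.
#' @export
rank_association <- function(delta, z) {
  ok <- stats::complete.cases(delta, z)
  delta <- delta[ok]
  z <- z[ok]
  if (length(delta) < 3) stop("need >= 3 paired non-missing values")
  if (stats::sd(delta) == 0 || stats::sd(z) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(delta)))
  ct <- suppressWarnings(
    stats::cor.test(delta, z, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(delta))
}
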