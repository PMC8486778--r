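#' Per-cell scATAC quality metrics
#'
#' Computes, per barcode, the total fragment count (sum of the count
#' column) and FrIP, the count-weighted fraction of fragments
#' overlapping any peak by at least one bp. FrIP is invariant to
#' merging or splitting a peak set covering the same base pairs, because
#' peaks are merged before overlap so a fragment spanning several peaks
#' is counted once.
#'
#' @param fragments Fragments `data.frame`.
#' @param peaks Peak regions; an empty set gives FrIP 0 with a warning.
#' @param barcodes Optional barcodes to report even when absent from
#'   `fragments` (reported with 0 fragments and undefined FrIP).
#' @return `data.frame` with columns `barcode`, `total_fragments`,
#'   `frip` (`NA` when no fragments).
#' @export
compute_atac_qc <- function(fragments, peaks, barcodes = NULL) {
  all_bc <- sort(unique(c(fragments$barcode, barcodes)))
  total <- rep(0, length(all_bc))
  names(total) <- all_bc
  obs <- tapply(fragments$count, fragments$barcode, sum)
  total[names(obs)] <- obs
  in_peak <- rep(0, length(all_bc))
  names(in_peak) <- all_bc
  peaks <- .merge_regions(peaks)
  if (nrow(peaks) == 0) {
    warning("empty peak set: FrIP is 0 for all cells")
  } else if (nrow(fragments)) {
    hit <- IRanges::overlapsAny(.as_granges(fragments),
                                      .as_granges(peaks))
    if (any(hit)) {
      obs <- tapply(fragments$count[hit], fragments$barcode[hit], sum)
      in_peak[names(obs)] <- obs
    }
  }
  frip <- ifelse(total > 0, in_peak / total, NA_real_)
  data.frame(barcode = all_bc, total_fragments = as.numeric(total),
             frip = as.numeric(frip), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Filter scATAC cells on FrIP and fragment count
#'
#' Cells with FrIP below `frip_min` or total fragments below `frag_min`
#' are removed; removal is by strict inequality, so boundary cells
#' (FrIP exactly 0.2, exactly 1000 fragments) are retained. Cells with
#' undefined FrIP (no fragments) are removed.
#'
#' @param qc `data.frame` from [compute_atac_qc()].
#' @param frip_min FrIP threshold (default 0.2).
#' @param frag_min Fragment-count threshold (default 1000).
#' @return Character vector of kept barcodes.
#' @export
filter_atac_cells <- function(qc, frip_min = 0.2, frag_min = 1000) {
  keep <- !is.na(qc$frip) & qc$frip >= frip_min &
    qc$total_fragments >= frag_min
  qc$barcode[keep]
}

#' Filter snRNA cells on expressed genes and mitochondrial fraction
#'
#' Cells with fewer than `genes_min` genes expressed (UMI > 0) or more
#' than `mito_max` of their UMIs from mitochondrial genes are removed;
#' boundary cells are retained. Mitochondrial genes are identified by a
#' configurable name prefix.
#'
#' @param expr Counts matrix, genes x cells.
#' @param genes_min Minimum expressed genes (default 200).
#' @param mito_max Maximum mitochondrial UMI fraction (default 0.8).
#' @param mito_prefix Gene-name prefix marking mitochondrial genes
#'   (default `"MT-"`); if no gene matches, the mito filter is skipped
#'   with a warning.
#' @return Character vector of kept cell identifiers.
#' @export
filter_rna_cells <- function(expr, genes_min = 200, mito_max = 0.8,
                             mito_prefix = "MT-") {
  n_genes <- colSums(expr > 0)
  keep <- n_genes >= genes_min
  mito <- startsWith(rownames(expr), mito_prefix)
  if (!any(mito)) {
    warning("no genes match mito prefix '", mito_prefix,
            "'; mitochondrial filter skipped")
  } else {
    tot <- colSums(expr)
    mito_frac <- ifelse(tot > 0, colSums(expr[mito, , drop = FALSE]) / tot, 0)
    keep <- keep & mito_frac <= mito_max
  }
  colnames(expr)[keep]
}
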