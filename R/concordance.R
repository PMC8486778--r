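#' Per-cell fragment counts in marker promoter windows
#'
#' Count-weighted overlaps (any bp) of each cell's fragments with each
#' promoter region. The default promoter definition elsewhere in the
#' package is TSS +/- 2 kb.
#'
#' @param fragments Fragments `data.frame`.
#' @param promoters Regions `data.frame` with a `name` column.
#' @param barcodes Optional cells to report even with zero counts.
#' @param genome Optional [genome_model]; promoters outside the genome
#'   are an error.
#' @return Integer-valued matrix, cells x promoters.
#' @export
promoter_counts <- function(fragments, promoters, barcodes = NULL,
                            genome = NULL) {
  if (!is.null(genome)) {
    bad <- !(promoters$chrom %in% genome$chroms) |
      promoters$end > genome$lengths[promoters$chrom] |
      promoters$start < 0
    if (any(bad))
      stop("promoter(s) outside the genome: ",
           paste(promoters$name[bad], collapse = ", "))
  }
  all_bc <- sort(unique(c(fragments$barcode, barcodes)))
  out <- matrix(0, length(all_bc), nrow(promoters),
                dimnames = list(all_bc, promoters$name))
  if (nrow(fragments) == 0) return(out)
  fgr <- .as_granges(fragments)
  pgr <- .as_granges(promoters)
  hits <- GenomicRanges::findOverlaps(fgr, pgr)
  if (length(hits)) {
    fi <- S4Vectors::queryHits(hits)
    pj <- S4Vectors::subjectHits(hits)
    agg <- tapply(fragments$count[fi],
                  list(factor(fragments$barcode[fi], all_bc),
                       factor(pj, seq_len(nrow(promoters)))),
                  sum, default = 0)
    out[rownames(agg), ] <- agg
  }
  out
}

#' Call per-cell epigenetic labels from promoter accessibility
#'
#' Cells are gated tumor/normal on the SOX2 promoter (tumor iff count >=
#' `t_tumor`); tumor cells are then typed by the two subtype promoters:
#' ASCL1 if only the ASCL1 promoter is accessible, NEUROD1 if only the
#' NEUROD1 promoter is, and ambiguous when both or neither are. Presence
#' thresholds are binary (>= 1 fragment) because per-cell promoter
#' signals are near-binary at single-cell depth; the calls are invariant
#' to uniform depth scaling of a cell.
#'
#' @param counts Matrix from [promoter_counts()].
#' @param tumor_marker Column gating tumor vs normal (default "SOX2").
#' @param t_tumor Minimum tumor-marker count (default 1).
#' @param subtype_markers The two subtype promoter columns.
#' @return Named character vector of labels in
#'   `{normal, ASCL1, NEUROD1, ambiguous}`.
#' @export
call_cell_labels <- function(counts, tumor_marker = "SOX2", t_tumor = 1,
                             subtype_markers = c("ASCL1", "NEUROD1")) {
  for (m in c(tumor_marker, subtype_markers))
    if (!m %in% colnames(counts)) stop("missing marker column: ", m)
  a <- counts[, subtype_markers[1]] > 0
  b <- counts[, subtype_markers[2]] > 0
  lab <- rep("ambiguous", nrow(counts))
  lab[a & !b] <- subtype_markers[1]
  lab[b & !a] <- subtype_markers[2]
  lab[counts[, tumor_marker] < t_tumor] <- "normal"
  stats::setNames(lab, rownames(counts))
}

#' Score cells on top differential accessibility regions
#'
#' Per cell, fragments are counted over each subtype's top differential
#' region set and normalized by the cell's total fragment count, giving
#' depth-invariant accessibility scores; a cell is labelled by the
#' larger score when the ratio exceeds `margin`, otherwise ambiguous.
#'
#' @param fragments Fragments `data.frame`.
#' @param regions_a,regions_b Region `data.frame`s (e.g. the top 30
#'   differential regions of each subtype).
#' @param names Labels for the two sets (default ASCL1, NEUROD1).
#' @param margin Ratio of scores required for a call (default 1.5).
#' @param barcodes Optional cells to report even with zero counts.
#' @return `data.frame` with `barcode`, `score_a`, `score_b`, `label`.
#' @export
signature_accessibility_score <- function(fragments, regions_a, regions_b,
                                          names = c("ASCL1", "NEUROD1"),
                                          margin = 1.5, barcodes = NULL) {
  if (nrow(regions_a) == 0 || nrow(regions_b) == 0)
    stop("empty region set")
  all_bc <- sort(unique(c(fragments$barcode, barcodes)))
  total <- rep(0, length(all_bc))
  names(total) <- all_bc
  obs <- tapply(fragments$count, fragments$barcode, sum)
  total[names(obs)] <- obs
  count_set <- function(regions) {
    hit <- IRanges::overlapsAny(.as_granges(fragments),
                                      .as_granges(regions))
    v <- rep(0, length(all_bc))
    names(v) <- all_bc
    if (any(hit)) {
      o <- tapply(fragments$count[hit], fragments$barcode[hit], sum)
      v[names(o)] <- o
    }
    v
  }
  sa <- ifelse(total > 0, count_set(regions_a) / total, 0)
  sb <- ifelse(total > 0, count_set(regions_b) / total, 0)
  lab <- rep("ambiguous", length(all_bc))
  lab[sa > margin * sb & sa > 0] <- names[1]
  lab[sb > margin * sa & sb > 0] <- names[2]
  data.frame(barcode = all_bc, score_a = unname(sa), score_b = unname(sb),
             label = lab, stringsAsFactors = FALSE)
}

#' Concordance between epigenetic and genetic labelings
#'
#' Cross-tabulates per-cell epigenetic subtype labels against genetic
#' (CNV cluster) labels over their common cells, reporting the
#' contingency table, the adjusted Rand index and, per genetic cluster,
#' the fraction of its majority epigenetic label (so a genetically
#' coherent cluster whose cells split between two subtypes — a "mixed"
#' cluster — shows a purity near its mixing proportion). Ambiguous cells
#' are excluded and counted.
#'
#' @param epi Named character vector of epigenetic labels (by barcode);
#'   `"ambiguous"` entries are dropped.
#' @param genetic Named vector of genetic labels (by barcode), or the
#'   `data.frame` from [cluster_cells_by_cnv()].
#' @return List with `table`, `ari`, `purity` (named by genetic
#'   cluster), `n_cells`, `n_ambiguous`.
#' @export
concordance <- function(epi, genetic) {
  if (is.data.frame(genetic))
    genetic <- stats::setNames(genetic$genetic_label, genetic$barcode)
  ambiguous <- names(epi)[epi == "ambiguous"]
  epi <- epi[epi != "ambiguous"]
  common <- intersect(names(epi), names(genetic))
  if (length(common) == 0) stop("no cells shared between the labelings")
  e <- epi[common]
  g <- genetic[common]
  tab <- table(genetic = g, epigenetic = e)
  purity <- apply(tab, 1, function(r) max(r) / sum(r))
  list(table = tab,
       ari = adjusted_rand_index(g, e),
       purity = purity,
       n_cells = length(common),
       n_ambiguous = length(ambiguous))
}
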