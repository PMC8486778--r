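# Small in-code fixtures shared across test files. Everything is built
# programmatically; no data files.

frag_df <- function(chrom, start, end, barcode, count = 1) {
  data.frame(chrom = chrom, start = start, end = end, barcode = barcode,
             count = count, stringsAsFactors = FALSE)
}

region_df <- function(chrom, start, end, name = NULL) {
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(name)) out$name <- name
  out
}

# A small two-chromosome config for fast unit-level simulations. Markers
# are re-homed onto the small genome.
small_sim_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(
    seed = seed,
    chrom_lengths = c(chr1 = 40e6, chr2 = 30e6),
    window_size = 2e6,
    n_peaks = 60,
    n_cells = 24,
    frags_per_cell = 2000,
    frip_mean = 0.25, frip_conc = 200,
    markers = data.frame(name = c("SOX2", "INSM1", "ASCL1", "NEUROD1"),
                         chrom = c("chr1", "chr1", "chr2", "chr2"),
                         tss = c(5e6, 15e6, 5e6, 15e6),
                         strand = "+", stringsAsFactors = FALSE),
    clones = list(clone_truth("normal", 1, subtype = "normal")))
  defaults[names(args)] <- args # top-level replacement, no recursion
  do.call(sim_config, defaults)
}

# Brute-force FrIP: per fragment, any-bp overlap against the raw
# (unmerged) peak list, counted once per fragment record.
oracle_frip <- function(frags, peaks) {
  bcs <- sort(unique(frags$barcode))
  sapply(bcs, function(bc) {
    f <- frags[frags$barcode == bc, ]
    hit <- vapply(seq_len(nrow(f)), function(i) {
      any(peaks$chrom == f$chrom[i] &
            peaks$start < f$end[i] & f$start[i] < peaks$end)
    }, logical(1))
    sum(f$count[hit]) / sum(f$count)
  })
}

# Brute-force nearest-|dGC| background: repeated minimum scans with
# explicit tie-breaking by genomic rank, independent of order().
oracle_background <- function(windows, n_match) {
  usable <- which(!is.na(windows$gc) & windows$effective_length > 0)
  out <- vector("list", nrow(windows))
  for (q in usable) {
    cand <- setdiff(usable, q)
    d <- abs(windows$gc[cand] - windows$gc[q])
    picked <- integer(0)
    for (i in seq_len(min(n_match, length(cand)))) {
      remaining <- setdiff(seq_along(cand), picked)
      best <- remaining[1]
      for (j in remaining) {
        if (d[j] < d[best] || (d[j] == d[best] && cand[j] < cand[best]))
          best <- j
      }
      picked <- c(picked, best)
    }
    out[[q]] <- cand[picked]
  }
  out
}

# Brute-force signed KS running-sum score for one sample.
oracle_ks <- function(values, gene_names, sig_genes) {
  ord <- order(-values, gene_names)
  genes <- gene_names[ord]
  m <- sum(gene_names %in% sig_genes)
  N <- length(gene_names)
  rs <- 0
  best <- 0
  for (g in genes) {
    rs <- rs + if (g %in% sig_genes) 1 / m else -1 / (N - m)
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}
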