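#!/usr/bin/env Rscript
# Step 2 — per-cell quality control.
#
# Computes total fragments and FrIP per barcode and applies the
# inclusion filter (cells with FrIP < 0.2 or fewer than 1000 fragments
# are removed; boundary values are kept). Writes the QC table and the
# kept-barcode list.

library(clonescope)

genome <- local({
  gc <- read_bedgraph("scratch/simdata/gc.bedGraph")
  lens <- tapply(gc$end, gc$chrom, max)
  genome_model(unique(gc$chrom), lens[unique(gc$chrom)])
})
frags <- read_fragments("scratch/simdata/fragments.tsv.gz", genome)
peaks <- read_bed("scratch/simdata/peaks.bed")

qc <- compute_atac_qc(frags, peaks)
kept <- filter_atac_cells(qc, frip_min = 0.2, frag_min = 1000)

write.table(qc, "results/qc_cells.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(kept, "results/qc_kept_barcodes.txt")

message(sprintf("kept %d of %d cells (%.1f%%); FrIP median %.3f",
                length(kept), nrow(qc), 100 * length(kept) / nrow(qc),
                median(qc$frip, na.rm = TRUE)))
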