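#' Clone truth for the fragment simulator
#'
#' Describes one genetic clone: its copy-number events (baseline ploidy
#' 2), its share of the cell population, and the epigenetic subtype of
#' its cells. A clone may be a subtype mixture (`subtype_mix`), emulating
#' a genetic cluster whose cells split between the ASCL1 and NEUROD1
#' programs.
#'
#' @param id Clone identifier.
#' @param fraction Fraction of cells in this clone; fractions over all
#'   clones must sum to 1.
#' @param subtype Epigenetic subtype of the clone's cells (`"normal"`,
#'   `"ASCL1"` or `"NEUROD1"`).
#' @param subtype_mix Named probability vector over subtypes; overrides
#'   `subtype` and assigns each cell a subtype at random.
#' @param events `data.frame` with `chrom`, `start`, `end`, `copy`
#'   (integer copy number, 2 = neutral).
#' @return A `clone_truth` list.
#' @export
clone_truth <- function(id, fraction, subtype = "normal",
                        subtype_mix = NULL,
                        events = data.frame(chrom = character(),
                                            start = numeric(),
                                            end = numeric(),
                                            copy = numeric())) {
  if (nrow(events) && any(events$copy < 0))
    stop("copy numbers must be >= 0")
  if (!is.null(subtype_mix)) {
    if (is.null(names(subtype_mix)) || abs(sum(subtype_mix) - 1) > 1e-8)
      stop("'subtype_mix' must be a named probability vector summing to 1")
  }
  structure(list(id = id, fraction = fraction, subtype = subtype,
                 subtype_mix = subtype_mix, events = events),
            class = "clone_truth")
}

#' Default clone truths
#'
#' Three populations emulating the single-cell study design: a normal
#' clone with a flat genome, a NEUROD1-subtype clone carrying a 20 Mb
#' copy-4 amplification, and an ASCL1-subtype clone carrying a 10 Mb
#' single-copy loss, in equal proportions.
#'
#' @return List of [clone_truth] objects.
#' @export
default_clone_truths <- function() {
  list(
    clone_truth("normal", 1 / 3, subtype = "normal"),
    clone_truth("cloneA", 1 / 3, subtype = "NEUROD1",
                events = data.frame(chrom = "chr2", start = 60e6,
                                    end = 80e6, copy = 4)),
    clone_truth("cloneB", 1 / 3, subtype = "ASCL1",
                events = data.frame(chrom = "chr1", start = 100e6,
                                    end = 110e6, copy = 1)))
}

#' Default marker gene table
#'
#' TSS positions for the four marker genes used for promoter-based cell
#' typing on the synthetic genome: SOX2 (tumor gate), INSM1 (pan-NE) and
#' the two subtype factors ASCL1 and NEUROD1.
#'
#' @return `data.frame` with `name`, `chrom`, `tss`, `strand`.
#' @export
default_markers <- function() {
  data.frame(name = c("SOX2", "INSM1", "ASCL1", "NEUROD1"),
             chrom = c("chr3", "chr4", "chr5", "chr1"),
             tss = c(50e6, 60e6, 70e6, 30e6),
             strand = "+",
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic data generator. The defaults
#' are the study conditions used throughout the package's tests: a
#' fifteen-chromosome, ~3 Gb genome tiled into 1 Mb windows — human
#' genome scale, so that the 100 GC-matched background windows are a
#' selective (~3%) GC match as they are on real data — 600 cells in
#' three equal clones, about 25,000 fragments per cell at FrIP 0.25
#' (well over 5000 off-target fragments per cell, within the typical
#' droplet scATAC range), a linear GC-efficiency bias of slope 1, and
#' two 50-gene expression programs separated by 2 log2 units.
#'
#' @param seed Random seed (mandatory; all generator draws derive from
#'   it).
#' @param chrom_lengths Named numeric of chromosome lengths.
#' @param window_size Simulation window size in bp.
#' @param gc_mean,gc_sd,gc_smooth,gc_range Per-window GC field: a
#'   Gaussian field smoothed with a moving average of half-width
#'   `gc_smooth` windows (spatial autocorrelation) is rank-transformed
#'   to a uniform marginal on `gc_range`. `gc_sd = 0` gives a
#'   constant-GC genome at `gc_mean`.
#' @param gc_bias_slope Slope of the linear amplification-efficiency
#'   curve `eff(gc) = 1 + slope * (gc - 0.5)`; 0 switches the bias off.
#' @param n_peaks,peak_width Number and width of background accessible
#'   peaks.
#' @param n_cells Number of cells.
#' @param frags_per_cell,frags_sdlog Lognormal fragments-per-cell
#'   distribution (mean and sdlog).
#' @param frip_mean,frip_conc Beta-distributed per-cell FrIP target
#'   (mean and concentration).
#' @param fragment_length Fragment length in bp.
#' @param clones List of [clone_truth]s; fractions must sum to 1.
#' @param markers Marker table as in [default_markers()].
#' @param marker_frac Expected fraction of a cell's in-peak fragments
#'   landing in each active marker promoter peak.
#' @param marker_activity Named list: which markers are accessible in
#'   cells of each subtype.
#' @param program_size,n_background_genes Genes per expression program
#'   and number of unstructured background genes.
#' @param effect_log2fc,noise_sd,base_log2 Expression model: program
#'   effect size (log2), lognormal noise SD (log2 units), baseline.
#' @param n_samples,sample_weights Expression cohort size and per-sample
#'   ASCL1-program mixing weights in \[0, 1\] (1 = pure ASCL1-type);
#'   `NULL` alternates pure samples.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       chrom_lengths = c(
                         chr1 = 250e6, chr2 = 240e6, chr3 = 230e6,
                         chr4 = 220e6, chr5 = 210e6, chr6 = 205e6,
                         chr7 = 200e6, chr8 = 195e6, chr9 = 190e6,
                         chr10 = 185e6, chr11 = 180e6, chr12 = 175e6,
                         chr13 = 170e6, chr14 = 165e6, chr15 = 160e6),
                       window_size = 1e6,
                       gc_mean = 0.5, gc_sd = 0.08, gc_smooth = 5,
                       gc_range = c(0.3, 0.7),
                       gc_bias_slope = 1,
                       n_peaks = 2000, peak_width = 500,
                       n_cells = 600,
                       frags_per_cell = 25000, frags_sdlog = 0.2,
                       frip_mean = 0.25, frip_conc = 100,
                       fragment_length = 100,
                       clones = default_clone_truths(),
                       markers = default_markers(),
                       marker_frac = 0.005,
                       marker_activity = list(
                         normal = character(0),
                         ASCL1 = c("SOX2", "INSM1", "ASCL1"),
                         NEUROD1 = c("SOX2", "INSM1", "NEUROD1")),
                       program_size = 50, n_background_genes = 100,
                       effect_log2fc = 2, noise_sd = 0.5, base_log2 = 5,
                       n_samples = 20, sample_weights = NULL) {
  if (missing(seed)) stop("'seed' is mandatory")
  fr <- vapply(clones, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("clone fractions must sum to 1")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome and its per-window GC field
#'
#' Builds the genome model, tiles it into windows, and draws a smooth
#' (moving-average filtered) GC fraction per window, clipped to
#' `gc_range`. Deterministic under the config seed.
#'
#' @param config A [sim_config].
#' @return List with elements `genome` ([genome_model]) and `windows`
#'   (`genomic_windows` with `gc` filled).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  genome <- genome_model(names(config$chrom_lengths), config$chrom_lengths)
  windows <- make_windows(genome, config$window_size)
  if (config$gc_sd == 0) {
    windows$gc <- rep(config$gc_mean, nrow(windows))
    return(list(genome = genome, windows = windows))
  }
  k <- max(0, round(config$gc_smooth))
  z <- unlist(lapply(genome$chroms, function(ch) {
    n <- sum(windows$chrom == ch)
    x <- stats::rnorm(n + 2 * k)
    if (k > 0) {
      sm <- stats::filter(x, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
      x <- as.numeric(sm)[(k + 1):(k + n)]
    }
    x
  }))
  # Rank-transform the smooth field to a uniform marginal on gc_range:
  # spatial autocorrelation is preserved (the transform is monotone) and
  # every GC stratum is equally dense, so nearest-GC background matching
  # has symmetric neighborhoods everywhere except at the range edges.
  u <- (rank(z, ties.method = "first") - 0.5) / length(z)
  windows$gc <- unname(config$gc_range[1] +
                         u * diff(config$gc_range))
  list(genome = genome, windows = windows)
}

# Background accessible peaks plus one named promoter peak per marker.
.simulate_peaks <- function(config, genome) {
  per_chrom <- round(config$n_peaks * genome$lengths / sum(genome$lengths))
  peaks <- do.call(rbind, lapply(genome$chroms, function(ch) {
    n <- per_chrom[[ch]]
    starts <- sort(sample.int(genome$lengths[[ch]] - config$peak_width, n))
    data.frame(chrom = ch, start = as.numeric(starts),
               end = as.numeric(starts) + config$peak_width,
               name = "", stringsAsFactors = FALSE)
  }))
  peaks$name <- sprintf("peak%05d", seq_len(nrow(peaks)))
  m <- config$markers
  mpk <- data.frame(chrom = m$chrom, start = m$tss - 500, end = m$tss + 500,
                    name = m$name, stringsAsFactors = FALSE)
  out <- rbind(peaks, mpk)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a single-cell fragment file with planted CNV clones
#'
#' Cells are assigned to clones by the configured fractions; each cell
#' draws a sequencing depth (lognormal) and a FrIP target (Beta).
#' Off-target fragments are placed per (cell, window) by Poisson draws
#' with expectation proportional to copy number x GC efficiency x
#' effective window length, at positions uniform over the window's
#' non-peak sequence; in-peak fragments are placed in peaks drawn
#' according to the cell subtype's marker accessibility. Truth tables
#' are first-class outputs.
#'
#' @param config A [sim_config].
#' @return List with `fragments`, `cells` (barcode, clone, subtype),
#'   `events`, `peaks`, `windows`, `genome`, `config`.
#' @export
simulate_fragments <- function(config) {
  sg <- simulate_genome(config)
  genome <- sg$genome
  windows <- sg$windows
  set.seed(config$seed + 1L)
  peaks <- .simulate_peaks(config, genome)
  windows <- effective_window_size(windows, peaks)
  fraglen <- config$fragment_length

  # cells and clone assignment (deterministic rounding of fractions)
  n <- config$n_cells
  fr <- vapply(config$clones, `[[`, numeric(1), "fraction")
  sizes <- floor(fr * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(fr * n - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  if (any(sizes == 0))
    warning("clone(s) with zero cells omitted: ",
            paste(vapply(config$clones, `[[`, "", "id")[sizes == 0],
                  collapse = ", "))
  clone_of <- rep(seq_along(config$clones), sizes)
  barcodes <- sprintf("cell%04d", seq_len(n))
  subtype_of <- unlist(lapply(seq_along(config$clones), function(ci) {
    cl <- config$clones[[ci]]
    if (sizes[ci] == 0) return(character(0))
    if (!is.null(cl$subtype_mix))
      sample(names(cl$subtype_mix), sizes[ci], replace = TRUE,
             prob = cl$subtype_mix)
    else rep(cl$subtype, sizes[ci])
  }))

  # per-clone window copy number (overlap-fraction weighted)
  copy <- matrix(2, length(config$clones), nrow(windows))
  for (ci in seq_along(config$clones)) {
    ev <- config$clones[[ci]]$events
    if (is.null(ev) || nrow(ev) == 0) next
    for (ei in seq_len(nrow(ev))) {
      ov <- pmax(0, pmin(windows$end, ev$end[ei]) -
                    pmax(windows$start, ev$start[ei]))
      ov[windows$chrom != ev$chrom[ei]] <- 0
      frac <- ov / (windows$end - windows$start)
      copy[ci, ] <- copy[ci, ] + (ev$copy[ei] - 2) * frac
    }
  }

  depth <- round(stats::rlnorm(n, log(config$frags_per_cell) -
                                 config$frags_sdlog^2 / 2,
                               config$frags_sdlog))
  frip <- stats::rbeta(n, config$frip_mean * config$frip_conc,
                       (1 - config$frip_mean) * config$frip_conc)

  # ---- off-target fragments -----------------------------------------
  eff <- pmax(1 + config$gc_bias_slope * (windows$gc - 0.5), 0.05)
  usable <- .usable_windows(windows)
  pmat <- copy * rep(eff * windows$effective_length, each = nrow(copy))
  pmat[, !usable] <- 0
  pmat <- pmat / rowSums(pmat)
  lambda <- (depth * (1 - frip)) * pmat[clone_of, , drop = FALSE]
  cnt <- matrix(stats::rpois(length(lambda), lambda), nrow = n)
  nz <- which(cnt > 0, arr.ind = TRUE)
  reps <- cnt[nz]
  off_cell <- rep(nz[, 1], reps)
  off_win <- rep(nz[, 2], reps)

  # non-peak sub-intervals of each window, with start-position budgets
  wgr <- .as_granges(windows, genome)
  pgr <- GenomicRanges::reduce(.as_granges(peaks, genome))
  comp <- GenomicRanges::setdiff(wgr, pgr)
  h <- GenomicRanges::findOverlaps(comp, wgr)
  pieces <- IRanges::pintersect(comp[S4Vectors::queryHits(h)],
                                wgr[S4Vectors::subjectHits(h)])
  piece_win <- S4Vectors::subjectHits(h)
  piece_start <- GenomicRanges::start(pieces) - 1
  avail <- GenomicRanges::width(pieces) - fraglen
  keep <- avail > 0
  piece_win <- piece_win[keep]
  piece_start <- piece_start[keep]
  avail <- avail[keep]

  off_start <- rep(NA_integer_, length(off_win))
  ord <- order(off_win)
  off_cell <- off_cell[ord]
  off_win <- off_win[ord]
  run <- rle(off_win)
  pos0 <- cumsum(c(0, run$lengths))
  for (ri in seq_along(run$values)) {
    wv <- run$values[ri]
    pi <- which(piece_win == wv)
    if (!length(pi)) next # window with no placeable non-peak sequence
    cum <- cumsum(c(0, avail[pi]))
    u <- stats::runif(run$lengths[ri]) * cum[length(cum)]
    slot <- findInterval(u, cum, rightmost.closed = TRUE)
    slot[slot < 1] <- 1
    idx <- (pos0[ri] + 1):pos0[ri + 1]
    off_start[idx] <- as.integer(piece_start[pi][slot] +
                                   floor(u - cum[slot]))
  }
  placed <- !is.na(off_start)
  off_frags <- data.frame(chrom = windows$chrom[off_win[placed]],
                          start = off_start[placed],
                          end = off_start[placed] + as.integer(fraglen),
                          barcode = barcodes[off_cell[placed]],
                          count = 1L, stringsAsFactors = FALSE)

  # ---- in-peak fragments --------------------------------------------
  n_in <- stats::rpois(n, depth * frip)
  peak_is_marker <- peaks$name %in% config$markers$name
  in_list <- list()
  for (st in unique(subtype_of)) {
    cells_st <- which(subtype_of == st)
    tot <- sum(n_in[cells_st])
    if (tot == 0) next
    active <- config$marker_activity[[st]]
    if (is.null(active)) active <- character(0)
    prob <- numeric(nrow(peaks))
    is_active <- peaks$name %in% active
    prob[is_active] <- config$marker_frac
    n_bg <- sum(!peak_is_marker)
    prob[!peak_is_marker] <- (1 - sum(prob[is_active])) / n_bg
    pk <- sample.int(nrow(peaks), tot, replace = TRUE, prob = prob)
    room <- pmax(peaks$end[pk] - peaks$start[pk] - fraglen, 1)
    st_pos <- as.integer(peaks$start[pk] + floor(stats::runif(tot) * room))
    in_list[[st]] <- data.frame(
      chrom = peaks$chrom[pk], start = st_pos,
      end = st_pos + as.integer(fraglen),
      barcode = barcodes[rep(cells_st, n_in[cells_st])],
      count = 1L, stringsAsFactors = FALSE)
  }
  frags <- rbind(off_frags, do.call(rbind, in_list))
  ord <- order(match(frags$chrom, genome$chroms), frags$start)
  frags <- frags[ord, , drop = FALSE]
  rownames(frags) <- NULL

  events <- do.call(rbind, lapply(config$clones, function(cl) {
    if (is.null(cl$events) || nrow(cl$events) == 0) return(NULL)
    cbind(clone = cl$id, cl$events)
  }))
  list(fragments = frags,
       cells = data.frame(barcode = barcodes,
                          clone = vapply(config$clones, `[[`, "",
                                         "id")[clone_of],
                          subtype = subtype_of, stringsAsFactors = FALSE),
       events = events, peaks = peaks, windows = windows,
       genome = genome, config = config)
}

#' Simulate a subtype-structured expression matrix
#'
#' Two anti-correlated gene programs of `program_size` genes each (led
#' by the markers ASCL1 and NEUROD1) over a background of unstructured
#' genes. A sample with mixing weight w expresses the ASCL1 program at
#' `base + effect * w` and the NEUROD1 program at `base + effect *
#' (1 - w)` (log2 scale) with lognormal noise; values are returned on
#' the linear (TPM-like) scale.
#'
#' @param config A [sim_config].
#' @param weights Optional per-sample mixing weights overriding the
#'   config.
#' @return List with `expression` (genes x samples), `labels` (sample,
#'   weight, type) and `programs` (the two true gene sets).
#' @export
simulate_expression <- function(config, weights = NULL) {
  set.seed(config$seed + 2L)
  if (is.null(weights)) weights <- config$sample_weights
  if (is.null(weights))
    weights <- rep(c(1, 0), length.out = config$n_samples)
  ns <- length(weights)
  prog_a <- c("ASCL1", sprintf("PA%02d", seq_len(config$program_size - 1)))
  prog_b <- c("NEUROD1", sprintf("PB%02d", seq_len(config$program_size - 1)))
  bg <- sprintf("BG%03d", seq_len(config$n_background_genes))
  genes <- c(prog_a, prog_b, bg)
  samples <- sprintf("S%03d", seq_len(ns))
  mu <- matrix(config$base_log2, length(genes), ns,
               dimnames = list(genes, samples))
  mu[prog_a, ] <- mu[prog_a, ] +
    rep(config$effect_log2fc * weights, each = length(prog_a))
  mu[prog_b, ] <- mu[prog_b, ] +
    rep(config$effect_log2fc * (1 - weights), each = length(prog_b))
  logexpr <- mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                         nrow(mu))
  expr <- 2^logexpr
  labels <- data.frame(sample = samples, weight = weights,
                       type = ifelse(weights >= 0.5, "ASCL1", "NEUROD1"),
                       stringsAsFactors = FALSE)
  list(expression = expr, labels = labels,
       programs = list(ASCL1 = prog_a, NEUROD1 = prog_b))
}

#' Write a simulated data set to disk
#'
#' Writes `fragments.tsv(.gz)`, `peaks.bed`, `gc.bedGraph`,
#' `truth_cells.tsv` and `truth_events.tsv` so downstream steps can run
#' purely from files.
#'
#' @param sim Result of [simulate_fragments()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress the fragments file.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fragments(sim$fragments,
                  file.path(dir, if (gzip) "fragments.tsv.gz"
                            else "fragments.tsv"))
  write_bed(sim$peaks, file.path(dir, "peaks.bed"))
  gc_track <- data.frame(chrom = sim$windows$chrom,
                         start = sim$windows$start,
                         end = sim$windows$end,
                         value = sim$windows$gc)
  utils::write.table(gc_track, file.path(dir, "gc.bedGraph"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$cells, file.path(dir, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$events))
    utils::write.table(sim$events, file.path(dir, "truth_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Promoter windows for marker genes
#'
#' @param markers Marker table (`name`, `chrom`, `tss`).
#' @param flank Half-width of the promoter window around the TSS
#'   (default 2000 bp).
#' @return Regions `data.frame` with a `name` column.
#' @export
marker_promoters <- function(markers, flank = 2000) {
  data.frame(chrom = markers$chrom,
             start = pmax(markers$tss - flank, 0),
             end = markers$tss + flank,
             name = markers$name, stringsAsFactors = FALSE)
}
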