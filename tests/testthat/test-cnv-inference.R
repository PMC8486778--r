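test_that("window tiling handles exact division, remainders and short chroms", {
  gm <- genome_model(c("c10", "c5.5", "c4.5", "c1"),
                     c(10e6, 5.5e6, 4.5e6, 1.2e6))
  w <- make_windows(gm, 2e6)
  expect_equal((w$end - w$start)[w$chrom == "c10"], rep(2e6, 5))
  expect_equal((w$end - w$start)[w$chrom == "c5.5"], c(2e6, 2e6, 1.5e6))
  expect_equal((w$end - w$start)[w$chrom == "c4.5"], c(2e6, 2.5e6))
  expect_equal((w$end - w$start)[w$chrom == "c1"], 1.2e6)
  # tiling: contiguous, no overlap, covers each chromosome
  for (ch in gm$chroms) {
    wc <- w[w$chrom == ch, ]
    expect_equal(wc$start, c(0, utils::head(wc$end, -1)))
    expect_equal(utils::tail(wc$end, 1), unname(gm$lengths[ch]))
  }
})

test_that("window GC from sequence excludes ambiguous bases", {
  gm <- genome_model("chr1", 40)
  w <- make_windows(gm, 10)
  seqs <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("AC", 5),                 # win1: 0.5
                  strrep("A", 10),                 # win2: 0
                  strrep("N", 5), "GCGCG",         # win3: 1 (N excluded)
                  strrep("N", 10))))               # win4: all N -> NA
  w <- window_gc(w, sequence = seqs)
  expect_equal(w$gc, c(0.5, 0, 1, NA))
  expect_false(tail(w$gc, 1) %in% 0:1) # flagged unusable
  # bedGraph path agrees with direct assignment
  track <- data.frame(chrom = "chr1", start = c(0, 20), end = c(20, 40),
                      value = c(0.25, 0.75))
  w2 <- window_gc(make_windows(gm, 10), gc_track = track)
  expect_equal(w2$gc, c(0.25, 0.25, 0.75, 0.75))
})

test_that("effective window size subtracts exactly the in-window peak bp", {
  gm <- genome_model("chr1", 6e6)
  w <- make_windows(gm, 2e6)
  peaks <- region_df("chr1",
                     c(100000, 150000, 1950000),
                     c(200000, 250000, 2100000))
  w2 <- effective_window_size(w, peaks)
  # merged peak bp in window 1: [100k,250k) = 150k, plus [1.95M,2M) = 50k
  expect_equal(w2$effective_length[1], 2e6 - 150000 - 50000)
  # boundary-spanning peak contributes only its in-window part
  expect_equal(w2$effective_length[2], 2e6 - 100000)
  expect_equal(w2$effective_length[3], 2e6)
  expect_equal(effective_window_size(w, peaks[0, ])$effective_length,
               rep(2e6, 3))
})

make_cov_fixture <- function() {
  gm <- genome_model(c("chr1", "chr2"), c(10e6, 10e6))
  w <- make_windows(gm, 2e6)
  w$gc <- seq(0.35, 0.65, length.out = nrow(w))
  w
}

test_that("window coverage is depth-invariant and peak-compensated", {
  w <- make_cov_fixture()
  set.seed(1)
  n <- 5000
  frags <- frag_df(sample(c("chr1", "chr2"), n, TRUE),
                   s <- sample.int(10e6 - 200, n), s + 100, "cell1", 1)
  cov1 <- window_coverage(frags, w)
  expect_equal(mean(cov1), 1)
  frags5 <- frags
  frags5$count <- frags$count * 5
  expect_equal(window_coverage(frags5, w), cov1) # scale invariance
  expect_equal(window_coverage(frags5, w, collapse_duplicates = TRUE),
               cov1)

  # a window with half its bp in peaks but unchanged off-target rate
  # keeps its normalized coverage (effective-length compensation)
  peak <- region_df("chr1", 0, 1e6)
  in_peak <- frags$chrom == "chr1" & frags$start < 1e6
  off <- frags[!in_peak, ]
  w2 <- effective_window_size(w, peak)
  cov2 <- window_coverage(off, w2, peaks = peak)
  expect_equal(unname(cov2[1, 1]), unname(cov1[1, 1]), tolerance = 0.1)
})

test_that("fragments are assigned to windows by midpoint", {
  w <- make_cov_fixture()
  # fragment spanning the window-1/window-2 boundary, midpoint in window 2
  frags <- rbind(frag_df("chr1", 1999990, 2000110, "c", 1), # mid 2000050
                 frag_df("chr1", 1999890, 2000010, "c", 1)) # mid 1999950
  cov <- window_coverage(frags, w)
  counts <- cov[1, ] > 0
  expect_equal(sum(counts), 2)
  expect_true(counts[1] && counts[2])
})

test_that("GC-matched background equals the brute-force oracle", {
  set.seed(7)
  for (rep in 1:5) {
    gm <- genome_model("chr1", 60e6)
    w <- make_windows(gm, 2e6)
    w$gc <- round(runif(nrow(w), 0.3, 0.7), 2) # rounding forces ties
    n_match <- sample(3:12, 1)
    expect_identical(gc_matched_background(w, n_match),
                     oracle_background(w, n_match))
  }
})

test_that("background matching follows exhaustion and tie-break rules", {
  gm <- genome_model("chr1", 100e6)
  w <- make_windows(gm, 2e6) # 50 windows
  w$gc <- runif(nrow(w), 0.3, 0.7)
  expect_warning(bg <- gc_matched_background(w, 100), "fewer than")
  expect_true(all(vapply(bg, length, 1L) == 49))
  expect_false(any(vapply(seq_along(bg), function(i) i %in% bg[[i]],
                          logical(1))))
  # constant GC: matches are the first n other windows in genomic order
  w$gc <- 0.5
  bg <- gc_matched_background(w, 10)
  expect_equal(bg[[1]], 2:11)
  expect_equal(bg[[25]], c(1:10))
  expect_equal(bg[[5]], c(1:4, 6:11))
})

test_that("fold change against background follows its definition", {
  w <- make_cov_fixture()
  w$gc <- 0.5
  bg <- gc_matched_background(w, 4)
  cov <- matrix(1, 1, nrow(w), dimnames = list("e", window_id(w)))
  expect_equal(unname(cnv_fold_change(cov, bg)[1, ]), rep(0, 10))
  cov[1, 3] <- 2 # exactly 2x its (unit) background
  lfc <- cnv_fold_change(cov, bg)
  expect_equal(unname(lfc[1, 3]), log2(2.01 / 1.01))
  expect_equal(unname(lfc[1, 3]), 1, tolerance = 0.02)
})

test_that("locus readout is a length-weighted window mean", {
  w <- make_cov_fixture()
  lfc <- rep(0, nrow(w))
  lfc[1:2] <- c(1, -1)
  # locus covering 1 Mb of window 1 and 3 Mb of windows 2 (2 Mb is full)
  locus <- list(chrom = "chr1", start = 1e6, end = 4e6)
  expect_equal(locus_cn(lfc, w, locus), (1 * 1 + (-1) * 2) / 3)
  expect_equal(locus_cn(rep(0, nrow(w)), w,
                        list(chrom = "chr2", start = 0, end = 1e6)), 0)
  expect_true(is.na(locus_cn(c(NA, lfc[-1]), w,
                             list(chrom = "chr1", start = 0, end = 1e6))))
})

test_that("profile correlation handles identity, negation and sparsity", {
  set.seed(3)
  x <- rnorm(40)
  m <- rbind(a = x, b = x, c = -x)
  r <- correlate_profiles(m)
  expect_equal(unname(r["a", "b"]), 1)
  expect_equal(unname(r["a", "c"]), -1)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r, t(r))
  m2 <- rbind(a = c(x, rep(NA, 40)), b = c(rep(NA, 38), x[1:2], rep(NA, 40)))
  r2 <- correlate_profiles(m2)
  expect_true(is.na(r2["a", "b"])) # only 2 shared windows
})

test_that("clone clustering is labeled deterministically and validates k", {
  set.seed(9)
  base <- matrix(rnorm(30 * 20, sd = 0.1), 30, 20)
  base[11:20, 1:5] <- base[11:20, 1:5] + 1
  base[21:30, 6:12] <- base[21:30, 6:12] - 1.5
  rownames(base) <- sprintf("c%02d", 1:30)
  cl <- cluster_cells_by_cnv(base, k = 3, seed = 4)
  # label 1 is the flattest (normal-like) cluster
  expect_true(all(cl$genetic_label[1:10] == 1))
  expect_equal(length(unique(cl$genetic_label[11:20])), 1)
  expect_equal(length(unique(cl$genetic_label[21:30])), 1)
  # duplicated cells co-cluster; k = 1 puts everyone together
  dup <- base[c(1, 1, 15, 15), ]
  rownames(dup) <- c("u1", "u2", "v1", "v2")
  cld <- cluster_cells_by_cnv(rbind(base, dup), k = 3, seed = 4)
  expect_equal(cld$genetic_label[cld$barcode == "u1"],
               cld$genetic_label[cld$barcode == "u2"])
  expect_equal(cld$genetic_label[cld$barcode == "v1"],
               cld$genetic_label[cld$barcode == "v2"])
  expect_true(all(cluster_cells_by_cnv(base, k = 1,
                                       seed = 1)$genetic_label == 1))
  expect_error(cluster_cells_by_cnv(base[1:2, ], k = 3, seed = 1),
               "fewer cells")
})

test_that("adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(11)
  for (i in 1:20) {
    x <- sample(1:4, 60, TRUE)
    y <- sample(letters[1:3], 60, TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y))
  }
  x <- sample(1:3, 50, TRUE)
  expect_equal(adjusted_rand_index(x, x), 1)
  # symmetry and label-permutation invariance
  y <- sample(1:3, 50, TRUE)
  expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
  expect_equal(adjusted_rand_index(x, y),
               adjusted_rand_index(x, c(3, 1, 2)[y]))
})

test_that("CNV-free profiles average to zero log2 fold change", {
  cfg <- small_sim_config(seed = 19, n_cells = 30, frags_per_cell = 5000)
  sim <- simulate_fragments(cfg)
  cov <- window_coverage(sim$fragments, sim$windows, sim$peaks,
                         grouping = setNames(rep("all", nrow(sim$cells)),
                                             sim$cells$barcode))
  bg <- suppressWarnings(gc_matched_background(sim$windows, 100))
  lfc <- cnv_fold_change(cov, bg)
  expect_lt(abs(mean(lfc, na.rm = TRUE)), 0.05)
})
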