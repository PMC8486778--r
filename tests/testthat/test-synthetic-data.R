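test_that("simulated genome GC field is bounded, smooth and reproducible", {
  cfg <- small_sim_config(seed = 5)
  sg <- simulate_genome(cfg)
  expect_equal(nrow(sg$windows), 35) # 20 + 15 windows of 2 Mb
  expect_true(all(sg$windows$gc >= 0.3 & sg$windows$gc <= 0.7))
  # spatial autocorrelation: neighbours are closer in GC than random pairs
  gc <- sg$windows$gc[sg$windows$chrom == "chr1"]
  expect_lt(mean(abs(diff(gc))), mean(abs(outer(gc, gc, "-"))))
  sg2 <- simulate_genome(small_sim_config(seed = 5))
  expect_identical(sg$windows$gc, sg2$windows$gc)

  flat <- simulate_genome(small_sim_config(seed = 5, gc_sd = 0))
  expect_true(all(flat$windows$gc == 0.5))
})

test_that("fragment simulation is deterministic and passes validation", {
  cfg <- small_sim_config(seed = 7)
  sim <- simulate_fragments(cfg)
  sim2 <- simulate_fragments(small_sim_config(seed = 7))
  expect_identical(sim$fragments, sim2$fragments)
  expect_identical(sim$cells, sim2$cells)
  # validation is a no-op on generator output
  expect_identical(validate_fragments(sim$fragments, sim$genome),
                   sim$fragments)
  expect_equal(sort(unique(sim$fragments$barcode)),
               sort(sim$cells$barcode))
})

test_that("null model: flat GC and no events give uniform coverage", {
  cfg <- small_sim_config(seed = 13, gc_sd = 0, gc_bias_slope = 0,
                          n_cells = 20, frags_per_cell = 20000)
  sim <- simulate_fragments(cfg)
  cov <- window_coverage(sim$fragments, sim$windows, sim$peaks,
                         grouping = setNames(rep("all", nrow(sim$cells)),
                                             sim$cells$barcode))
  expect_equal(unname(cov["all", ]), rep(1, ncol(cov)), tolerance = 0.05)
})

test_that("a planted copy-4 event doubles expected window coverage", {
  ev <- data.frame(chrom = "chr1", start = 10e6, end = 20e6, copy = 4)
  cfg <- small_sim_config(
    seed = 17, gc_sd = 0, gc_bias_slope = 0, n_cells = 20,
    frags_per_cell = 20000,
    clones = list(clone_truth("tum", 1, subtype = "ASCL1", events = ev)))
  sim <- simulate_fragments(cfg)
  cov <- window_coverage(sim$fragments, sim$windows, sim$peaks,
                         grouping = setNames(rep("all", nrow(sim$cells)),
                                             sim$cells$barcode))
  in_ev <- sim$windows$chrom == "chr1" & sim$windows$start >= 10e6 &
    sim$windows$end <= 20e6
  ratio <- mean(cov["all", in_ev]) / mean(cov["all", !in_ev])
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("observed FrIP matches the configured target", {
  cfg <- small_sim_config(seed = 23, frip_mean = 0.5, frip_conc = 1e6,
                          n_cells = 5, frags_per_cell = 10000)
  sim <- simulate_fragments(cfg)
  qc <- compute_atac_qc(sim$fragments, sim$peaks)
  # ~10000 fragments at p = 0.5: the binomial 99.9% envelope is ~0.017
  expect_true(all(abs(qc$frip - 0.5) < 0.02))
})

test_that("zero-fraction clones are omitted with a warning", {
  cfg <- small_sim_config(
    seed = 3, n_cells = 10,
    clones = list(clone_truth("normal", 1, subtype = "normal"),
                  clone_truth("ghost", 0, subtype = "ASCL1")))
  expect_warning(sim <- simulate_fragments(cfg), "ghost")
  expect_true(all(sim$cells$clone == "normal"))
})

test_that("expression generator separates programs by the stated effect", {
  cfg0 <- small_sim_config(seed = 31, effect_log2fc = 0, n_samples = 20)
  ex0 <- simulate_expression(cfg0)
  la <- log2(ex0$expression[ex0$programs$ASCL1, ])
  lb <- log2(ex0$expression[ex0$programs$NEUROD1, ])
  expect_lt(abs(mean(la) - mean(lb)), 0.1) # null: indistinguishable

  cfg2 <- small_sim_config(seed = 31, effect_log2fc = 2, noise_sd = 0.5)
  ex2 <- simulate_expression(cfg2, weights = rep(c(1, 0), 10))
  a_type <- ex2$labels$type == "ASCL1"
  sep <- mean(log2(ex2$expression[ex2$programs$ASCL1, a_type])) -
    mean(log2(ex2$expression[ex2$programs$ASCL1, !a_type]))
  expect_equal(sep, 2, tolerance = 0.15)

  # analytic mixture mean: at w = 0.5 the ASCL1 marker sits halfway
  exm <- simulate_expression(cfg2, weights = rep(0.5, 200))
  expect_equal(mean(log2(exm$expression["ASCL1", ])),
               cfg2$base_log2 + 1, tolerance = 0.15)
  expect_identical(simulate_expression(cfg2)$expression,
                   simulate_expression(cfg2)$expression)
})

test_that("written simulations can be consumed by the io layer", {
  cfg <- small_sim_config(seed = 41, n_cells = 6, frags_per_cell = 500)
  sim <- simulate_fragments(cfg)
  dir <- tempfile()
  write_simulation(sim, dir)
  frags <- read_fragments(file.path(dir, "fragments.tsv.gz"),
                          genome = sim$genome)
  expect_equal(frags, sim$fragments)
  peaks <- read_bed(file.path(dir, "peaks.bed"))
  expect_equal(peaks[, c("chrom", "start", "end")],
               sim$peaks[, c("chrom", "start", "end")])
  gc <- read_bedgraph(file.path(dir, "gc.bedGraph"))
  expect_equal(gc$value, sim$windows$gc)
})
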