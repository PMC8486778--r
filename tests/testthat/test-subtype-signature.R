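test_that("differential test agrees with per-feature Welch t-tests", {
  set.seed(21)
  counts <- matrix(rpois(50 * 8, 60), 50, 8,
                   dimnames = list(sprintf("f%02d", 1:50), NULL))
  groups <- rep(c("A", "B"), each = 4)
  res <- differential_test(counts, groups)
  libsize <- colSums(counts)
  L <- log2(sweep(counts, 2, libsize / mean(libsize), "/") + 1)
  for (i in c(1, 17, 50)) {
    tt <- t.test(L[i, groups == "B"], L[i, groups == "A"])
    expect_equal(res$p_value[i], tt$p.value)
    expect_equal(res$log2_fold_change[i], unname(diff(rev(tt$estimate))))
  }
  expect_equal(res$adjusted_p, p.adjust(res$p_value, "BH"))
  # BH keeps the adjusted p monotone in the raw-p ranking
  ord <- order(res$p_value)
  expect_true(all(diff(res$adjusted_p[ord]) >= 0))
})

test_that("differential test null and planted-effect behaviour", {
  set.seed(22)
  counts <- matrix(rpois(100 * 10, 50), 100, 10,
                   dimnames = list(sprintf("g%03d", 1:100), NULL))
  groups <- rep(c("A", "B"), each = 5)
  # identical groups by construction: duplicate columns
  same <- counts[, c(1:5, 1:5)]
  res0 <- differential_test(same, groups)
  expect_equal(res0$log2_fold_change, rep(0, 100))
  expect_equal(res0$p_value, rep(1, 100))
  # planted 4-fold feature at low noise
  counts["g001", groups == "B"] <- rpois(5, 800)
  counts["g001", groups == "A"] <- rpois(5, 200)
  res <- differential_test(counts, groups)
  expect_equal(res$log2_fold_change[res$feature == "g001"], 2,
               tolerance = 0.25)
  expect_lt(res$adjusted_p[res$feature == "g001"], 0.05)
})

test_that("region thresholds implement both study modes", {
  res <- data.frame(
    feature = c("r1", "r2", "r3", "r4", "r5"),
    log2_fold_change = c(2.5, 1.5, -1.5, 2.5, 0.5),
    p_value = c(1e-5, 1e-3, 1e-4, 2e-3, 0.5),
    adjusted_p = c(5e-4, 0.02, 5e-3, 2e-3, 0.6))
  expect_equal(apply_region_thresholds(res, "ne_vs_ad"), "r1")
  sub <- apply_region_thresholds(res, "subtype")
  expect_equal(sub$up, c("r1", "r4"))
  expect_equal(sub$down, "r3")
  # idempotence: filtering the kept set again changes nothing
  res2 <- res[res$feature %in% c(sub$up, sub$down), ]
  sub2 <- apply_region_thresholds(res2, "subtype")
  expect_equal(sub2, sub)
  expect_error(apply_region_thresholds(res, "other"))
})

test_that("peak-TSS linking honours the 50 kb rule and tie-breaks", {
  tss <- data.frame(gene = c("GENE_B", "GENE_A", "FAR"),
                    chrom = c("chr1", "chr1", "chr2"),
                    tss = c(100000, 140000, 9e6))
  summits <- data.frame(chrom = c("chr1", "chr2", "chr1", "chr1", "chr2"),
                        pos = c(100000 - 49999, # 49,999 bp from GENE_B
                                9e6 + 50001,    # 50,001 bp from FAR
                                110000, 120000, 1e6),
                        name = c("in_range", "just_out", "nearest",
                                 "tie", "too_far"))
  links <- link_peaks_to_genes(summits, tss)
  expect_equal(links$gene[links$summit == "in_range"], "GENE_B")  # 49,999
  expect_true(is.na(links$gene[links$summit == "just_out"]))      # 50,001
  expect_equal(links$gene[links$summit == "nearest"], "GENE_B")   # 10 vs 30 kb
  expect_equal(links$gene[links$summit == "tie"], "GENE_A")       # tie: id
  expect_true(is.na(links$gene[links$summit == "too_far"]))
  expect_error(link_peaks_to_genes(summits,
                                   rbind(tss, tss[1, ])), "duplicate")
})

test_that("signature construction scores and ranks deterministically", {
  res <- data.frame(feature = c("g1", "g2", "g3"),
                    log2_fold_change = c(2, 3, -4),
                    p_value = c(0.01, 1, 1e-6),
                    adjusted_p = c(0.02, 1, 1e-5))
  sig <- suppressWarnings(build_signature(res, n = 2, name = "demo"))
  expect_s3_class(sig, "signature_set")
  expect_equal(sig$scores[sig$genes == "g1"], 2 * -log10(0.01)) # = 4
  # p = 1 scores 0 and never outranks an upregulated gene with p < 1
  expect_equal(sig$genes, c("g1", "g2"))
  # brute-force oracle on a random 20-gene table
  set.seed(5)
  tab <- data.frame(feature = sprintf("g%02d", 1:20),
                    log2_fold_change = rnorm(20, mean = 1),
                    p_value = runif(20))
  tab$adjusted_p <- p.adjust(tab$p_value, "BH")
  sig10 <- build_signature(tab, n = 10)
  up <- tab[tab$log2_fold_change > 0, ]
  sc <- up$log2_fold_change * -log10(up$p_value)
  oracle <- utils::head(up$feature[order(-sc, up$feature)], 10)
  expect_equal(sig10$genes, oracle)
  expect_warning(build_signature(tab, n = 50), "eligible")
  # eligibility restriction drops unlinked genes
  sig_r <- suppressWarnings(build_signature(tab, genes = up$feature[1:3]))
  expect_true(all(sig_r$genes %in% up$feature[1:3]))
})

test_that("KS enrichment hits the extremes and matches the oracle", {
  set.seed(6)
  genes <- sprintf("G%03d", 1:30)
  x <- matrix(sort(rnorm(30), decreasing = TRUE), 30, 1,
              dimnames = list(genes, "s1"))
  expect_equal(unname(ks_enrichment(x, genes[1:5])["s1"]), 1)
  expect_equal(unname(ks_enrichment(x, genes[26:30])["s1"]), -1)
  # hand-checkable case: 10 genes, hits at ranks 1, 4, 8
  g10 <- sprintf("H%02d", 1:10)
  y <- matrix(10:1, 10, 1, dimnames = list(g10, "s"))
  got <- unname(ks_enrichment(y, g10[c(1, 4, 8)])["s"])
  expect_equal(got, oracle_ks(y[, 1], g10, g10[c(1, 4, 8)]))
  expect_equal(got, 1 / 3 + 1 / 3 - 2 / 7) # running sum peak after rank 4
  # random instances vs brute force
  for (i in 1:20) {
    N <- sample(20:60, 1)
    gn <- sprintf("g%03d", 1:N)
    v <- matrix(rnorm(N), N, 1, dimnames = list(gn, "s"))
    sig <- sample(gn, sample(3:10, 1))
    expect_equal(unname(ks_enrichment(v, sig)["s"]),
                 oracle_ks(v[, 1], gn, sig))
  }
})

test_that("KS score is invariant under monotone transforms", {
  set.seed(8)
  gn <- sprintf("g%03d", 1:50)
  v <- matrix(abs(rnorm(50)) + 0.1, 50, 2, dimnames = list(gn, c("a", "b")))
  sig <- sample(gn, 8)
  base <- ks_enrichment(v, sig)
  expect_equal(ks_enrichment(exp(v), sig), base)
  expect_equal(ks_enrichment(v^3, sig), base)
  expect_equal(ks_enrichment(log(v), sig), base)
})

test_that("missing signature genes are dropped with a warning", {
  gn <- sprintf("g%03d", 1:20)
  v <- matrix(rnorm(20), 20, 1, dimnames = list(gn, "s"))
  expect_warning(sc <- ks_enrichment(v, c(gn[1:4], "absent")), "absent")
  expect_false(is.na(sc["s"]))
  expect_true(is.na(suppressWarnings(ks_enrichment(v, "absent"))["s"]))
})

test_that("delta is antisymmetric and the TF ratio is standardized", {
  a <- c(0.5, 0.2, -0.1)
  b <- c(0.1, 0.4, 0.3)
  expect_equal(subtype_delta(a, b), -subtype_delta(b, a))
  expect_equal(subtype_delta(a, a), rep(0, 3))
  expect_true(is.na(subtype_delta(c(a, NA), c(b, 1))[4]))

  set.seed(10)
  expr <- matrix(rexp(2 * 12, 0.1), 2, 12,
                 dimnames = list(c("ASCL1", "NEUROD1"), sprintf("s%02d", 1:12)))
  z <- normalized_tf_ratio(expr)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  raw <- (expr["ASCL1", ] + 1) / (expr["NEUROD1", ] + 1)
  expect_equal(order(z), order(raw)) # monotone in the raw ratio
  expect_error(normalized_tf_ratio(expr[, 1, drop = FALSE]), "2 samples")
  same <- matrix(1, 2, 5, dimnames = list(c("ASCL1", "NEUROD1"), NULL))
  expect_warning(z0 <- normalized_tf_ratio(same), "zero variance")
  expect_true(all(z0 == 0))
})

test_that("rank association reproduces exact Spearman limits", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(rank_association(x, x * 2 + 1)$rho, 1)
  expect_equal(rank_association(x, rev(x))$rho, -1)
  ra <- rank_association(c(x, NA), c(rev(x), 3))
  expect_equal(ra$n, 5)
  expect_true(is.na(rank_association(rep(1, 5), x)$rho))
  expect_error(rank_association(1:2, 2:1), ">= 3")
})
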