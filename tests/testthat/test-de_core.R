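test_that("expression filter implements the CPM-in-enough-samples rule", {
  # pad every library to exactly 10000 reads so CPM = count * 100:
  # "kept" has CPM (120, 10, 20, 150, 110, 30) -> 3 samples >= 100 CPM
  base <- rbind(kept = c(1.2, 0.1, 0.2, 1.5, 1.1, 0.3),
                gone = rep(0.5, 6),
                high = rep(10, 6))
  counts <- matrix(as.integer(base * 100), 3, 6,
                   dimnames = list(rownames(base), NULL))
  pad <- as.integer(10000 - colSums(counts))
  cm <- make_cm(rbind(counts, pad = pad))
  f <- filter_expressed(cm, cpm_min = 100 * 100, min_samples = 3)
  expect_true("kept" %in% f$gene_ids)
  expect_false("gone" %in% f$gene_ids)
  expect_true("high" %in% f$gene_ids)
  # order preserved
  expect_identical(f$gene_ids, intersect(cm$gene_ids, f$gene_ids))
  # degenerate threshold keeps everything
  expect_identical(filter_expressed(cm, cpm_min = 0)$gene_ids, cm$gene_ids)
  # everything removed is an explicit error
  expect_error(filter_expressed(cm, cpm_min = 1e9), "no genes pass")
})

test_that("TMM factors: identical columns give 1, geometric mean is 1, edgeR agrees", {
  m <- matrix(rep(c(10L, 200L, 3000L, 40L, 500L), 4), 5, 4)
  colnames(m) <- sprintf("s%d", 1:4)
  cm <- make_cm(m, groups = stats::setNames(rep(c("control", "knockout"), 2),
                                            colnames(m)))
  expect_equal(unname(tmm_factors(cm)), rep(1, 4))

  set.seed(31)
  r <- matrix(stats::rnbinom(300 * 6, mu = 200, size = 5), 300, 6)
  r[r == 0] <- 1L
  cmr <- make_cm(r)
  f <- tmm_factors(cmr)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  f_edger <- edgeR::calcNormFactors(r, method = "TMM")
  expect_equal(unname(f), unname(f_edger), tolerance = 1e-8)
})

test_that("TMM handles a pure depth difference by scaling, not factors", {
  set.seed(7)
  base <- stats::rnbinom(200, mu = 300, size = 10) + 1L
  m <- cbind(s1 = base, s2 = 2L * base, s3 = base, s4 = base)
  cm <- make_cm(m, groups = stats::setNames(rep(c("control", "knockout"), 2),
                                            colnames(m)))
  f <- tmm_factors(cm)
  # no composition change: factors stay 1, the depth lives in the library
  # sizes, and the equalized pseudo-counts agree across samples
  expect_equal(unname(f), rep(1, 4), tolerance = 1e-9)
  ps <- betastab:::pseudo_counts(m, colSums(m) * f)
  expect_equal(ps[, "s2"], ps[, "s1"], tolerance = 1e-9)
  # brute-force weighted trimmed mean against the first sample as reference
  f_ref <- tmm_factors(cm, ref = "s1")
  lib <- colSums(m)
  M <- log2((m[, 2] / lib[2]) / (m[, 1] / lib[1]))
  expect_equal(log2(f_ref[["s2"]] / f_ref[["s1"]]), mean(M), tolerance = 1e-9)
})

test_that("zero-total sample is an error", {
  m <- cbind(s1 = c(1L, 2L), s2 = c(0L, 0L))
  rownames(m) <- c("a", "b")
  cm <- count_matrix(m, c(s1 = "control", s2 = "knockout"))
  expect_error(tmm_factors(cm), "zero total")
})

test_that("dispersion estimation recovers the truth and respects the Poisson floor", {
  sim <- simulate_exon_intron_counts(
    2000, 3, truth_config = list(dispersion = 0, frac_stabilized = 0,
                                 frac_transcription = 0), seed = 15)
  phi0 <- estimate_dispersion(sim$exon)
  expect_equal(stats::median(phi0), 0)

  sim1 <- simulate_exon_intron_counts(
    2000, 3, truth_config = list(dispersion = 0.1, frac_stabilized = 0,
                                 frac_transcription = 0), seed = 16)
  phi1 <- estimate_dispersion(sim1$exon)
  expect_gt(stats::median(phi1), 0.05)
  expect_lt(stats::median(phi1), 0.2)

  # constant gene: identical counts => zero dispersion
  # (equal library sizes via a balancing gene, so counts stay untouched)
  other <- c(10L, 60L, 20L, 80L, 30L, 90L)
  m <- rbind(flat = rep(50L, 6), other = other, balance = 100L - other)
  cm <- make_cm(m)
  expect_equal(unname(estimate_dispersion(cm)["flat"]), 0)

  single <- make_cm(matrix(c(5L, 9L), 1, 2,
                           dimnames = list("g", c("ctl_1", "ko_1"))))
  expect_error(estimate_dispersion(single), "replication")
})

test_that("exact NB test: exchangeable null gives p = 1", {
  m <- cbind(ctl_1 = c(10L, 100L), ctl_2 = c(20L, 50L),
             ko_1 = c(10L, 100L), ko_2 = c(20L, 50L))
  rownames(m) <- c("a", "b")
  de <- nb_test(make_cm(m), dispersion = 0.1)
  expect_equal(de$p_value, c(1, 1))
  expect_equal(de$log_fc, c(0, 0))
})

test_that("exact NB test at phi = 0 equals exhaustive conditional enumeration", {
  m <- cbind(ctl_1 = 100L, ctl_2 = 110L, ko_1 = 400L, ko_2 = 380L)
  rownames(m) <- "g"
  cm <- count_matrix(m, stats::setNames(c("control", "control", "knockout",
                                          "knockout"), colnames(m)))
  # equal library sizes here, so pseudo-counts equal raw counts
  de <- nb_test(cm, lib_sizes = rep(1, 4), dispersion = 0)
  p_oracle <- enum_conditional_p(100 + 110, 400 + 380, 2, 2)
  expect_equal(de$p_value, p_oracle, tolerance = 1e-10)
  # a second configuration, including an unbalanced design
  m2 <- cbind(ctl_1 = 30L, ctl_2 = 45L, ctl_3 = 38L, ko_1 = 80L, ko_2 = 95L)
  rownames(m2) <- "g"
  cm2 <- count_matrix(m2, stats::setNames(c(rep("control", 3),
                                            rep("knockout", 2)),
                                          colnames(m2)))
  de2 <- nb_test(cm2, lib_sizes = rep(1, 5), dispersion = 0)
  expect_equal(de2$p_value, enum_conditional_p(30 + 45 + 38, 80 + 95, 3, 2),
               tolerance = 1e-10)
})

test_that("p-values are invariant to rescaling a sample with its library size", {
  sim <- simulate_exon_intron_counts(300, 3, seed = 19)
  cm <- sim$exon
  de1 <- nb_test(cm, lib_sizes = colSums(cm$counts), dispersion = 0.1)
  m2 <- cm$counts
  m2[, 1] <- m2[, 1] * 3L
  cm2 <- count_matrix(m2, stats::setNames(cm$samples$group,
                                          cm$samples$sample), "exon")
  lib2 <- colSums(cm$counts)
  lib2[1] <- lib2[1] * 3
  de2 <- nb_test(cm2, lib_sizes = lib2, dispersion = 0.1)
  # library equalization is exact up to the quantile adjustment's common
  # scale (which moves with the libraries) and the integer rounding of the
  # conditional test's group sums
  expect_equal(de2$p_value, de1$p_value, tolerance = 0.01)
  expect_lt(max(abs(de2$log_fc - de1$log_fc)), 0.02)
  expect_gt(stats::cor(de2$p_value, de1$p_value), 0.9999)
})

test_that("type-I error stays near nominal across dispersions", {
  for (phi in c(0.05, 0.2)) {
    sim <- simulate_exon_intron_counts(
      2000, 3, truth_config = list(dispersion = phi, frac_stabilized = 0,
                                   frac_transcription = 0),
      seed = 100 + round(100 * phi))
    de <- run_de(sim$exon)
    expect_gt(mean(de$p_value < 0.05), 0.03)
    expect_lt(mean(de$p_value < 0.05), 0.07)
  }
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (k in 1:5) {
    p <- stats::runif(20)
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
  expect_error(bh_fdr(c(0.1, NaN)), "finite")
  expect_error(bh_fdr(c(0.1, 1.4)), "0, 1")
  # adjusted values never fall below raw values
  p <- stats::runif(50)
  expect_true(all(bh_fdr(p) >= p - 1e-12))
})
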