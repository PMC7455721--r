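de_frame <- function(ids, lfc, p = NULL, fdr = NULL) {
  n <- length(ids)
  out <- data.frame(gene_id = ids, log_fc = lfc,
                    mean_cpm = rep(5, n),
                    p_value = if (is.null(p)) rep(0.5, n) else p,
                    fdr = if (is.null(fdr)) rep(0.5, n) else fdr,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

test_that("delta is the exon minus intron log fold change", {
  e <- de_frame(c("a", "b"), c(2.0, 3.0))
  i <- de_frame(c("a", "b"), c(0.5, 3.0))
  r <- delta_exon_intron(e, i)
  expect_equal(r$delta, c(1.5, 0))
  expect_equal(r$delta, r$exon_logfc - r$intron_logfc)

  # genes missing from one class are dropped with a message
  i2 <- de_frame(c("a", "c"), c(0.5, 1))
  expect_message(r2 <- delta_exon_intron(e, i2), "excluded")
  expect_identical(r2$gene_id, "a")
  expect_error(delta_exon_intron(e, de_frame("z", 1)), "no genes shared")
})

test_that("a strongly stabilized record classifies as stabilized", {
  # the flagship case: delta-exon-intron logFC 4.76 at FDR 1.7e-17
  rec <- data.frame(gene_id = "Slc5a10", exon_logfc = 5.0, intron_logfc = 0.24,
                    delta = 4.76, stringsAsFactors = FALSE)
  inter <- data.frame(gene_id = "Slc5a10", p_interaction = 1e-19,
                      fdr = 1.7e-17, stringsAsFactors = FALSE)
  exon_de <- de_frame("Slc5a10", 5.0, p = 1e-10, fdr = 1e-8)
  cl <- classify_targets(rec, inter, exon_de)
  expect_equal(cl$records$class, "stabilized_up")
  expect_equal(cl$summary$n_stabilized, 1L)
})

test_that("overlap accounting reproduces the stabilized/upregulated split", {
  n <- 400
  ids <- sprintf("g%03d", seq_len(n))
  # 317 stabilized genes, 254 of them also significantly up
  stab <- seq_len(317)
  up <- seq_len(254)
  rec <- data.frame(gene_id = ids, exon_logfc = 1, intron_logfc = 0,
                    delta = ifelse(seq_len(n) %in% stab, 1, -0.1),
                    stringsAsFactors = FALSE)
  inter <- data.frame(gene_id = ids,
                      p_interaction = ifelse(seq_len(n) %in% stab, 1e-6, 0.9),
                      fdr = ifelse(seq_len(n) %in% stab, 1e-4, 0.9),
                      stringsAsFactors = FALSE)
  exon_de <- de_frame(ids, lfc = rep(1, n),
                      fdr = ifelse(seq_len(n) %in% up, 0.01, 0.5))
  cl <- classify_targets(rec, inter, exon_de)
  expect_equal(cl$summary$n_stabilized, 317L)
  expect_equal(cl$summary$n_stabilized_and_up, 254L)
  expect_equal(cl$summary$n_stabilized_not_up, 63L)
  expect_equal(cl$summary$fraction_up, 254 / 317, tolerance = 1e-12)
  expect_equal(round(cl$summary$fraction_up, 2), 0.80)
})

test_that("empty stabilized set yields zeros with a warning", {
  rec <- data.frame(gene_id = "a", exon_logfc = 0, intron_logfc = 0,
                    delta = 0, stringsAsFactors = FALSE)
  inter <- data.frame(gene_id = "a", p_interaction = 0.9, fdr = 0.9,
                      stringsAsFactors = FALSE)
  expect_warning(cl <- classify_targets(rec, inter, de_frame("a", 0)),
                 "no stabilized")
  expect_equal(cl$summary$fraction_up, 0)
  expect_error(classify_targets(rec, inter, de_frame("a", 0),
                                fdr_alpha = 1.5), "0, 1")
})

test_that("reference overlap is a case-normalized sorted intersection", {
  o <- overlap_with_reference(c("a", "B", "c"), c("b", "C", "d"))
  expect_equal(o$genes, c("B", "C"))
  expect_equal(o$n, 2L)
  expect_equal(overlap_with_reference(c("a", "b"), c("x", "y"))$n, 0L)
  self <- overlap_with_reference(c("b", "a"), c("a", "b"))
  expect_equal(self$genes, c("A", "B"))
})

test_that("interaction test has power on strong single-gene stability shifts", {
  hits <- 0L
  for (k in 1:200) {
    sim <- simulate_exon_intron_counts(
      1, 3, truth_config = list(mu_range = c(500, 500), frac_stabilized = 1,
                                frac_transcription = 0, stab_logfc = 2,
                                dispersion = 0.1),
      seed = 1000 + k)
    p <- test_interaction(sim$exon, sim$intron)$p_interaction
    if (p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.9)
})

test_that("interaction p-values are uniform under the null", {
  sim <- simulate_exon_intron_counts(
    5000, 3, truth_config = list(frac_stabilized = 0,
                                 frac_transcription = 0), seed = 52)
  p <- test_interaction(sim$exon, sim$intron)$p_interaction
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("identical exon and intron tables give delta 0 and no significance", {
  sim <- simulate_exon_intron_counts(100, 3, seed = 53)
  ex <- sim$exon
  as_intron <- count_matrix(ex$counts,
                            stats::setNames(ex$samples$group,
                                            ex$samples$sample), "intron")
  de <- nb_test(ex, dispersion = 0.1)
  r <- delta_exon_intron(de, de)
  expect_true(all(r$delta == 0))
  p <- test_interaction(ex, as_intron)$p_interaction
  expect_true(all(p > 0.999))
})

test_that("delta is invariant to a global library rescaling of both classes", {
  sim <- simulate_exon_intron_counts(200, 3, seed = 54)
  lib <- colSums(sim$exon$counts)
  de_e1 <- nb_test(sim$exon, lib_sizes = lib, dispersion = 0.1)
  de_i1 <- nb_test(sim$intron, lib_sizes = lib, dispersion = 0.1)
  de_e2 <- nb_test(sim$exon, lib_sizes = 7 * lib, dispersion = 0.1)
  de_i2 <- nb_test(sim$intron, lib_sizes = 7 * lib, dispersion = 0.1)
  d1 <- delta_exon_intron(de_e1, de_i1)$delta
  d2 <- delta_exon_intron(de_e2, de_i2)$delta
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("delta is unbiased for the planted stability effect at high counts", {
  sim <- simulate_exon_intron_counts(
    800, 3, truth_config = list(mu_range = c(300, 1000), frac_stabilized = 1,
                                frac_transcription = 0, stab_logfc = 1),
    seed = 55)
  res <- analyze_stability(sim$exon, sim$intron)
  r <- merge(res$records, sim$truth, by = "gene_id")
  expect_lt(abs(mean(r$delta - r$stab_logfc)), 0.1)
})
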