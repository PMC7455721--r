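test_that("all generators are deterministic under a fixed seed", {
  a <- simulate_exon_intron_counts(50, 3, seed = 42)
  b <- simulate_exon_intron_counts(50, 3, seed = 42)
  expect_identical(a$exon$counts, b$exon$counts)
  expect_identical(a$intron$counts, b$intron$counts)
  expect_identical(a$truth, b$truth)

  ta <- simulate_traces(6, planted_blocks = list(list(cells = 1:3, rho = 0.5)),
                        seed = 9)
  tb <- simulate_traces(6, planted_blocks = list(list(cells = 1:3, rho = 0.5)),
                        seed = 9)
  expect_identical(ta$traces$F, tb$traces$F)

  da <- simulate_decay(seed = 5)
  db <- simulate_decay(seed = 5)
  expect_identical(da, db)

  mix <- data.frame(length_nt = c(80, 20), weight = c(0.6, 0.4))
  ga <- simulate_densitogram(mix, noise_sd = 0.001, seed = 3)
  gb <- simulate_densitogram(mix, noise_sd = 0.001, seed = 3)
  expect_identical(ga$intensity, gb$intensity)
})

test_that("exon counts track transcription plus stability, introns transcription only", {
  # one gene, many replicates: the sample-mean oracle
  sim <- simulate_exon_intron_counts(
    1, n_reps = 5000,
    truth_config = list(mu_range = c(2000, 2000), frac_stabilized = 1,
                        frac_transcription = 0, stab_logfc = 1.5,
                        dispersion = 0.1),
    seed = 11)
  grp <- sim$exon$samples$group
  lfc <- function(m) {
    log2(mean(m[, grp == "knockout"]) / mean(m[, grp == "control"]))
  }
  expect_equal(lfc(sim$exon$counts), 1.5, tolerance = 0.05)
  expect_equal(lfc(sim$intron$counts), 0, tolerance = 0.05)
})

test_that("the null generative case has equal group means (Poisson limit)", {
  sim <- simulate_exon_intron_counts(
    1, n_reps = 5000,
    truth_config = list(mu_range = c(500, 500), frac_stabilized = 0,
                        frac_transcription = 0, dispersion = 0),
    seed = 2)
  grp <- sim$exon$samples$group
  m1 <- mean(sim$exon$counts[, grp == "control"])
  m2 <- mean(sim$exon$counts[, grp == "knockout"])
  expect_equal(m2 / m1, 1, tolerance = 0.02)
  # Poisson limit: variance close to the mean
  expect_equal(stats::var(as.numeric(sim$exon$counts)) / mean(sim$exon$counts),
               1, tolerance = 0.1)
})

test_that("intron fold changes are independent of the stability effect", {
  sim <- simulate_exon_intron_counts(4000, 3, seed = 13)
  grp <- sim$exon$samples$group
  m <- sim$intron$counts
  ilfc <- log2((rowMeans(m[, grp == "knockout"]) + 0.125) /
                 (rowMeans(m[, grp == "control"]) + 0.125))
  # transcription shifts do move intron counts (by design), so they are a
  # covariate; the stability coefficient must be null
  fit <- stats::lm(ilfc ~ sim$truth$stab_logfc + sim$truth$tx_logfc)
  expect_lt(abs(stats::coef(fit)["sim$truth$stab_logfc"]), 0.05)
})

test_that("generator rejects invalid arguments", {
  expect_error(simulate_exon_intron_counts(0, 3), "positive integer")
  expect_error(simulate_exon_intron_counts(10, 2.5), "positive integer")
  expect_error(simulate_exon_intron_counts(
    10, 3, truth_config = list(dispersion = -0.1)), "non-negative")
  expect_error(simulate_traces(5, planted_blocks =
                                 list(list(cells = 1:2, rho = 1))), "rho")
  expect_error(simulate_traces(5, epochs = default_epochs()[0, ]), "empty")
  expect_error(simulate_decay(half_lives = c(control = -1)), "positive")
  expect_error(simulate_densitogram(
    data.frame(length_nt = c(80, 20), weight = c(0.7, 0.4))), "sum to 1")
  expect_error(simulate_densitogram(
    data.frame(length_nt = 30, weight = 1),
    marker = data.frame(length_nt = c(10, 50), position = c(10, 50))),
    "monotone")
})

test_that("planted blocks reach the target correlation; other pairs do not", {
  one_epoch <- data.frame(name = "3G", start_s = 0, end_s = 999)
  st <- simulate_traces(12, epochs = one_epoch,
                        planted_blocks = list(list(cells = 1:5, rho = 0.8),
                                              list(cells = 6:9, rho = 0.8)),
                        epoch_amplitudes = c("3G" = 0), seed = 21)
  R <- stats::cor(t(st$traces$F))
  within1 <- R[1:5, 1:5][upper.tri(R[1:5, 1:5])]
  expect_equal(mean(within1), 0.8, tolerance = 0.05)
  cross <- as.vector(R[1:5, 6:9])
  expect_lt(abs(mean(cross)), 0.1)
  # truth adjacency: symmetric, false diagonal, block co-membership
  A <- st$truth$adjacency
  expect_true(all(A == t(A)))
  expect_false(any(diag(A)))
  expect_true(all(A[1:5, 1:5][upper.tri(A[1:5, 1:5])]))
  expect_false(any(A[1:5, 6:12]))
})

test_that("independent cells decorrelate as traces grow", {
  one_epoch <- data.frame(name = "3G", start_s = 0, end_s = 1999)
  st <- simulate_traces(8, epochs = one_epoch,
                        epoch_amplitudes = c("3G" = 0), seed = 5)
  R <- stats::cor(t(st$traces$F))
  expect_lt(mean(abs(R[upper.tri(R)])), 0.06)
})

test_that("epoch means rise under stimulation", {
  st <- simulate_traces(6, seed = 8)
  ts <- st$traces
  m3 <- mean(ts$F[, betastab:::epoch_window(ts, "3G")])
  m17 <- mean(ts$F[, betastab:::epoch_window(ts, "17G")])
  mk <- mean(ts$F[, betastab:::epoch_window(ts, "KCl")])
  expect_gt(m17, m3 * 1.2)
  expect_gt(mk, m17)
})

test_that("decay generator matches the closed form and is unbiased", {
  d <- simulate_decay(c(control = 4), cv = 0, n_reps = 1)
  expect_equal(d$relative_abundance, c(100, 50, 25))
  flat <- simulate_decay(c(control = Inf), cv = 0, n_reps = 1)
  expect_equal(flat$relative_abundance, c(100, 100, 100))
  # Monte-Carlo mean at 4 h over 500 replicates within 1% of 50
  noisy <- simulate_decay(c(control = 4), cv = 0.05, n_reps = 500, seed = 77)
  m4 <- mean(noisy$relative_abundance[noisy$time_hr == 4])
  expect_equal(m4, 50, tolerance = 0.01 * 50)
})

test_that("densitograms integrate to one and place mass per the mixture", {
  single <- simulate_densitogram(data.frame(length_nt = 30, weight = 1))
  area <- betastab:::trapezoid(single$position, single$intensity)
  expect_equal(area, 1, tolerance = 1e-6)
  expect_lt(fraction_above(single, 50), 0.01)
  mix <- simulate_densitogram(
    data.frame(length_nt = c(80, 20), weight = c(0.6, 0.4)))
  expect_equal(fraction_above(mix, 50), 0.6, tolerance = 0.02)
})
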