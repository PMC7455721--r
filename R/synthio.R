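#' Simulate paired exon/intron count matrices with known ground truth
#'
#' Generates the data model behind exon-intron split stability analysis.
#' Intronic reads track transcription only: the knockout-group intron mean is
#' the control mean times \code{2^tx_logfc}. Exonic reads track transcription
#' and stability: the knockout exon mean is scaled by
#' \code{2^(tx_logfc + stab_logfc)}.
#'
#' Biological replicate variation acts on transcription and therefore on the
#' exonic and intronic reads of a gene in the same sample jointly: a per
#' gene-by-sample Gamma(1/phi, phi) factor (mean 1, variance phi) scales both
#' means before Poisson sampling. Marginally each count is exactly
#' NB(mu, phi) with variance mu + phi * mu^2; within a sample the exon and
#' intron counts of a gene are positively coupled, as they are in real
#' RNA-seq replicates.
#'
#' @param n_genes number of genes.
#' @param n_reps replicates per group (two groups: control, knockout).
#' @param truth_config list of effect-size settings:
#'   \describe{
#'     \item{mu_range}{range of per-sample expected exon counts at the nominal
#'       library size (default \code{c(100, 1000)}, uniform).}
#'     \item{intron_fraction}{intron mean as a fraction of the exon mean
#'       (default 0.1; intronic coverage is far below exonic).}
#'     \item{frac_stabilized, frac_transcription}{fractions of genes given a
#'       stability / transcription effect (defaults 0.1 each, disjoint).}
#'     \item{stab_logfc, tx_logfc}{log2 effect sizes (defaults 1.5).}
#'     \item{dispersion}{NB dispersion phi, scalar or per-gene vector
#'       (default 0.1). Zero gives the Poisson limit.}
#'   }
#' @param lib_sizes per-sample library-size multipliers relative to their mean
#'   (default: all equal). Length \code{2 * n_reps}.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with elements \code{exon} and \code{intron}
#'   (\code{\link{count_matrix}} objects) and \code{truth}, a data frame with
#'   columns \code{gene_id}, \code{tx_logfc}, \code{stab_logfc},
#'   \code{dispersion}, \code{mu_exon}, \code{mu_intron}.
#' @export
simulate_exon_intron_counts <- function(n_genes, n_reps = 3,
                                        truth_config = list(),
                                        lib_sizes = NULL, seed = 1L) {
  if (length(n_genes) != 1 || n_genes < 1 || n_genes != round(n_genes)) {
    stop("n_genes must be a positive integer")
  }
  if (length(n_reps) != 1 || n_reps < 1 || n_reps != round(n_reps)) {
    stop("n_reps must be a positive integer")
  }
  cfg <- utils::modifyList(list(mu_range = c(100, 1000),
                                intron_fraction = 0.1,
                                frac_stabilized = 0.1,
                                frac_transcription = 0.1,
                                stab_logfc = 1.5,
                                tx_logfc = 1.5,
                                dispersion = 0.1),
                           truth_config)
  phi <- rep_len(cfg$dispersion, n_genes)
  if (any(phi < 0)) stop("dispersion must be non-negative")
  n_samp <- 2L * as.integer(n_reps)
  if (is.null(lib_sizes)) lib_sizes <- rep(1, n_samp)
  if (length(lib_sizes) != n_samp || any(lib_sizes <= 0)) {
    stop("lib_sizes must be positive, one per sample")
  }
  rel_lib <- lib_sizes / mean(lib_sizes)
  set.seed(seed)

  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  mu_e <- stats::runif(n_genes, cfg$mu_range[1], cfg$mu_range[2])
  mu_i <- cfg$intron_fraction * mu_e
  stab <- numeric(n_genes)
  tx <- numeric(n_genes)
  n_s <- round(cfg$frac_stabilized * n_genes)
  n_t <- round(cfg$frac_transcription * n_genes)
  if (n_s + n_t > n_genes) stop("effect fractions exceed 1")
  idx <- sample.int(n_genes, n_s + n_t)
  stab[idx[seq_len(n_s)]] <- cfg$stab_logfc
  if (n_t > 0) tx[idx[n_s + seq_len(n_t)]] <- cfg$tx_logfc

  group <- rep(c("control", "knockout"), each = n_reps)
  exon <- matrix(0L, n_genes, n_samp)
  intron <- matrix(0L, n_genes, n_samp)
  pos <- phi > 0
  for (s in seq_len(n_samp)) {
    u <- rep(1, n_genes)
    if (any(pos)) {
      u[pos] <- stats::rgamma(sum(pos), shape = 1 / phi[pos],
                              scale = phi[pos])
    }
    fe <- if (group[s] == "knockout") 2^(tx + stab) else rep(1, n_genes)
    fi <- if (group[s] == "knockout") 2^tx else rep(1, n_genes)
    exon[, s] <- stats::rpois(n_genes, rel_lib[s] * u * mu_e * fe)
    intron[, s] <- stats::rpois(n_genes, rel_lib[s] * u * mu_i * fi)
  }
  dimnames(exon) <- dimnames(intron) <-
    list(gene_ids, sprintf("%s_%d", group, rep(seq_len(n_reps), 2)))
  groups <- stats::setNames(group, colnames(exon))
  list(exon = count_matrix(exon, groups, "exon"),
       intron = count_matrix(intron, groups, "intron"),
       truth = data.frame(gene_id = gene_ids, tx_logfc = tx,
                          stab_logfc = stab, dispersion = phi,
                          mu_exon = mu_e, mu_intron = mu_i,
                          stringsAsFactors = FALSE))
}

#' Default stimulus-epoch layout for simulated islet recordings
#'
#' Low glucose (3G) for 3 min, high glucose (17G) for 5 min, then KCl
#' depolarization for 2 min, sampled at 1 s.
#'
#' @export
default_epochs <- function() {
  data.frame(name = c("3G", "17G", "KCl"),
             start_s = c(0, 180, 480),
             end_s = c(180, 480, 600),
             stringsAsFactors = FALSE)
}

#' Simulate calcium fluorescence traces with planted correlated blocks
#'
#' Cells within a planted block share a latent AR(1) signal so that the
#' expected pairwise Pearson correlation equals the block's \code{rho};
#' cells in different blocks (or in none) are independent. Stimulus epochs
#' add step changes to the baseline (rising under 17G and KCl by default).
#'
#' @param n_cells number of cells.
#' @param epochs stimulus windows (data frame name/start_s/end_s), ordered and
#'   non-overlapping; default \code{\link{default_epochs}()}.
#' @param planted_blocks list of blocks, each a list with elements
#'   \code{cells} (integer indices) and \code{rho} (target within-block
#'   correlation, 0 <= rho < 1). Default: none.
#' @param noise_sd fluorescence noise amplitude (arbitrary units).
#' @param epoch_amplitudes named step heights as a fraction of baseline,
#'   default \code{c("3G" = 0, "17G" = 0.5, "KCl" = 0.8)}.
#' @param dt_s sampling interval in seconds (default 1).
#' @param baseline mean basal fluorescence (arbitrary units, default 100).
#' @param ar_coef AR(1) coefficient of the latent block signal (default 0.8).
#' @param seed integer seed.
#' @return list with \code{traces} (a \code{\link{trace_set}}) and
#'   \code{truth}: list with \code{adjacency}, a symmetric boolean cell-pair
#'   matrix of block co-membership (FALSE diagonal), and \code{blocks}.
#' @export
simulate_traces <- function(n_cells, epochs = default_epochs(),
                            planted_blocks = list(), noise_sd = 5,
                            epoch_amplitudes = c("3G" = 0, "17G" = 0.5,
                                                 "KCl" = 0.8),
                            dt_s = 1, baseline = 100, ar_coef = 0.8,
                            seed = 1L) {
  if (n_cells < 2) stop("need at least two cells")
  if (nrow(epochs) == 0) stop("epochs must not be empty")
  for (b in planted_blocks) {
    if (is.null(b$cells) || is.null(b$rho)) {
      stop("each block needs elements 'cells' and 'rho'")
    }
    if (b$rho < 0 || b$rho >= 1) stop("block rho must satisfy 0 <= rho < 1")
    if (any(b$cells < 1 | b$cells > n_cells)) stop("block cell index out of range")
  }
  all_block_cells <- unlist(lapply(planted_blocks, `[[`, "cells"))
  if (anyDuplicated(all_block_cells)) stop("blocks must be disjoint")
  set.seed(seed)

  time_s <- seq(min(epochs$start_s), max(epochs$end_s), by = dt_s)
  nt <- length(time_s)
  step <- numeric(nt)
  for (i in seq_len(nrow(epochs))) {
    amp <- epoch_amplitudes[epochs$name[i]]
    if (is.na(amp)) amp <- 0
    # half-open windows; the final epoch keeps its endpoint
    upper <- if (epochs$end_s[i] >= max(epochs$end_s)) {
      time_s <= epochs$end_s[i]
    } else {
      time_s < epochs$end_s[i]
    }
    step[time_s >= epochs$start_s[i] & upper] <- amp
  }

  # unit-variance AR(1)
  ar1 <- function(n) {
    z <- numeric(n)
    z[1] <- stats::rnorm(1)
    innov_sd <- sqrt(1 - ar_coef^2)
    for (t in 2:n) z[t] <- ar_coef * z[t - 1] + stats::rnorm(1, sd = innov_sd)
    z
  }

  gains <- exp(stats::rnorm(n_cells, sd = 0.15))
  F <- matrix(0, n_cells, nt)
  shared <- lapply(planted_blocks, function(b) ar1(nt))
  block_of <- rep(NA_integer_, n_cells)
  rho_of <- rep(0, n_cells)
  for (bi in seq_along(planted_blocks)) {
    block_of[planted_blocks[[bi]]$cells] <- bi
    rho_of[planted_blocks[[bi]]$cells] <- planted_blocks[[bi]]$rho
  }
  for (c in seq_len(n_cells)) {
    eps <- stats::rnorm(nt)
    sig <- if (!is.na(block_of[c])) {
      sqrt(rho_of[c]) * shared[[block_of[c]]] + sqrt(1 - rho_of[c]) * eps
    } else {
      eps
    }
    F[c, ] <- gains[c] * (baseline * (1 + step) + noise_sd * sig)
  }
  rownames(F) <- sprintf("cell_%02d", seq_len(n_cells))

  adjacency <- matrix(FALSE, n_cells, n_cells,
                      dimnames = list(rownames(F), rownames(F)))
  for (b in planted_blocks) {
    adjacency[b$cells, b$cells] <- TRUE
  }
  diag(adjacency) <- FALSE
  coords <- data.frame(x = stats::runif(n_cells, 0, 100),
                       y = stats::runif(n_cells, 0, 100))
  list(traces = trace_set(time_s, F, epochs, coords),
       truth = list(adjacency = adjacency, blocks = planted_blocks))
}

#' Simulate actinomycin-D decay time courses
#'
#' Expected relative abundance follows first-order decay,
#' \code{100 * 2^(-t / t_half)}, with multiplicative lognormal noise of the
#' stated coefficient of variation (the lognormal is mean-1, so noisy values
#' are unbiased on the natural scale).
#'
#' @param half_lives named numeric vector of half-lives in hours, one per
#'   genotype (e.g. \code{c(control = 2, knockout = 6)}). \code{Inf} gives a
#'   flat 100\% course.
#' @param timepoints_hr hours after transcription arrest; must include 0.
#' @param n_reps replicates per genotype.
#' @param cv multiplicative noise fraction (0 = noiseless).
#' @param gene gene label carried through to the output.
#' @param seed integer seed.
#' @return data frame (class \code{decay_course}) with columns \code{gene},
#'   \code{genotype}, \code{replicate}, \code{time_hr},
#'   \code{relative_abundance} (percent of the noiseless t = 0 level).
#' @export
simulate_decay <- function(half_lives = c(control = 2, knockout = 6),
                           timepoints_hr = c(0, 4, 8), n_reps = 3,
                           cv = 0.05, gene = "gene_1", seed = 1L) {
  if (any(half_lives <= 0)) stop("half-lives must be positive")
  if (!any(timepoints_hr == 0)) stop("timepoints must include 0")
  if (cv < 0) stop("cv must be non-negative")
  if (is.null(names(half_lives))) {
    names(half_lives) <- sprintf("genotype_%d", seq_along(half_lives))
  }
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  out <- do.call(rbind, lapply(names(half_lives), function(g) {
    th <- half_lives[[g]]
    do.call(rbind, lapply(seq_len(n_reps), function(r) {
      mu <- 100 * 2^(-timepoints_hr / th)
      noise <- if (cv > 0) {
        stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else {
        rep(1, length(mu))
      }
      data.frame(gene = gene, genotype = g, replicate = r,
                 time_hr = timepoints_hr, relative_abundance = mu * noise,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("decay_course", "data.frame")
  out
}

#' Default size-marker calibration for simulated poly(A) gels
#'
#' Migration position decreases log-linearly with fragment length
#' (longer tails migrate less far).
#'
#' @export
default_marker <- function() {
  nt <- c(10, 20, 30, 50, 80, 120, 200, 300)
  data.frame(length_nt = nt, position = 130 - 20 * log(nt))
}

#' Simulate a poly(A)-tail gel densitogram
#'
#' The lane profile is a weighted sum of Gaussian bands. Band centres are the
#' migration positions of the component tail lengths under the marker
#' calibration; before noise the profile integrates (trapezoid) to exactly 1.
#'
#' @param tail_mixture data frame with columns \code{length_nt} and
#'   \code{weight}; weights must sum to 1.
#' @param spread band standard deviation in migration-position units.
#' @param marker calibration anchors, data frame \code{length_nt},
#'   \code{position}; must be monotone (longer tails at smaller positions).
#' @param n_points grid resolution of the profile.
#' @param noise_sd additive intensity noise (truncated at 0); default 0.
#' @param seed integer seed.
#' @return list of class \code{densitogram} with \code{position},
#'   \code{intensity} and \code{marker}.
#' @export
simulate_densitogram <- function(tail_mixture, spread = 2,
                                 marker = default_marker(), n_points = 500,
                                 noise_sd = 0, seed = 1L) {
  if (abs(sum(tail_mixture$weight) - 1) > 1e-8) {
    stop("mixture weights must sum to 1")
  }
  cal <- calibrate(marker)  # errors on non-monotone anchors
  set.seed(seed)
  centres <- predict_position(cal, tail_mixture$length_nt)
  position <- seq(min(marker$position), max(marker$position),
                  length.out = n_points)
  intensity <- rep(0, n_points)
  for (k in seq_len(nrow(tail_mixture))) {
    intensity <- intensity +
      tail_mixture$weight[k] * stats::dnorm(position, centres[k], spread)
  }
  area <- trapezoid(position, intensity)
  if (area <= 0) stop("degenerate profile")
  intensity <- intensity / area
  if (noise_sd > 0) {
    intensity <- pmax(0, intensity + stats::rnorm(n_points, sd = noise_sd))
  }
  structure(list(position = position, intensity = intensity, marker = marker),
            class = "densitogram")
}

# trapezoidal integral
trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
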