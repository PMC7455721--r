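#' Counts per million
#'
#' @param counts count matrix or \code{\link{count_matrix}}.
#' @param lib_sizes per-sample library sizes; default column sums.
#' @return matrix of CPM values.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(m, 2, lib_sizes / 1e6, "/")
}

#' Filter to expressed genes
#'
#' Retains genes with CPM >= \code{cpm_min} in at least \code{min_samples}
#' samples, computed on raw library sizes (pre-normalization). Gene order is
#' preserved.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param cpm_min CPM threshold (default 1).
#' @param min_samples required number of samples at or above the threshold
#'   (default 3).
#' @return the filtered \code{count_matrix}.
#' @export
filter_expressed <- function(cm, cpm_min = 1, min_samples = 3) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- rowSums(cpm(cm) >= cpm_min) >= min_samples
  if (!any(keep)) stop("no genes pass the expression filter")
  count_matrix(cm$counts[keep, , drop = FALSE],
               stats::setNames(cm$samples$group, cm$samples$sample),
               cm$feature_class)
}

#' Trimmed mean of M-values normalization factors
#'
#' Between-sample scaling factors computed as the weighted trimmed mean of
#' per-gene log2 expression ratios (M-values) against a reference sample,
#' trimming the most extreme M-values and the expression extremes (A-values),
#' with inverse asymptotic-variance weights. Factors are normalized so their
#' geometric mean is 1.
#'
#' @param cm a \code{\link{count_matrix}} (filtered).
#' @param trim_m two-sided M-value trim fraction (default 0.30).
#' @param trim_a two-sided A-value trim fraction (default 0.05).
#' @param ref reference sample name or index; default: the sample whose
#'   upper-quartile CPM is closest to the mean upper quartile.
#' @return named vector of per-sample scaling factors.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (ncol(m) < 2) stop("need at least two samples")
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("sample with zero total count: ", colnames(m)[which(lib == 0)[1]])
  }
  if (is.null(ref)) {
    f75 <- apply(sweep(m, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(ref)) {
    ref <- match(ref, colnames(m))
    if (is.na(ref)) stop("reference sample not found")
  }
  yr <- m[, ref]
  Lr <- lib[ref]
  fac <- vapply(seq_len(ncol(m)), function(s) {
    if (s == ref) return(1)
    ys <- m[, s]
    Ls <- lib[s]
    ok <- ys > 0 & yr > 0
    if (!any(ok)) return(1)
    M <- log2((ys[ok] / Ls) / (yr[ok] / Lr))
    A <- 0.5 * log2((ys[ok] / Ls) * (yr[ok] / Lr))
    w <- (Ls - ys[ok]) / (Ls * ys[ok]) + (Lr - yr[ok]) / (Lr * yr[ok])
    if (max(abs(M)) < 1e-6) return(1)
    # rank-based double trim on M and A
    n <- length(M)
    lo_m <- floor(n * trim_m) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1
    hi_a <- n + 1 - lo_a
    rm_ <- rank(M)
    ra <- rank(A)
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
    if (!any(keep)) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, 0)
  fac <- fac / exp(mean(log(fac)))
  stats::setNames(fac, colnames(m))
}

# Pseudo-counts equalized to a common (geometric-mean) effective library
# size. With a dispersion available, counts are quantile-matched through
# gamma approximations of the NB at the input and output means, which
# preserves the mean-variance relationship the conditional test assumes
# (plain linear rescaling would distort the variance by the scaling
# factor). Without a dispersion, linear scaling is used as the first-pass
# approximation. Identical effective libraries are a no-op.
pseudo_counts <- function(m, lib_eff, dispersion = NULL) {
  common <- exp(mean(log(lib_eff)))
  w <- lib_eff / common
  if (max(abs(w - 1)) < 1e-12) return(m)
  if (is.null(dispersion)) {
    return(sweep(m, 2, 1 / w, "*"))
  }
  phi <- max(dispersion, 0)
  mu_common <- rowMeans(sweep(m, 2, 1 / w, "*"))
  out <- m
  for (s in seq_len(ncol(m))) {
    mu_in <- mu_common * w[s]
    mu_out <- mu_common
    ok <- mu_in > 1e-8 & mu_out > 1e-8
    r_in <- 1 + phi * mu_in[ok]
    r_out <- 1 + phi * mu_out[ok]
    p <- stats::pgamma(m[ok, s], shape = mu_in[ok] / r_in, scale = r_in)
    # avoid infinities at the distribution edges
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    out[ok, s] <- stats::qgamma(p, shape = mu_out[ok] / r_out, scale = r_out)
    out[!ok, s] <- m[!ok, s] / w[s]
  }
  out
}

# conditional log-likelihood of within-group counts given their sums,
# per gene, at a single dispersion phi (equalized library sizes assumed)
cond_loglik <- function(m, group, phi) {
  ll <- numeric(nrow(m))
  for (k in unique(group)) {
    y <- m[, group == k, drop = FALSE]
    nk <- ncol(y)
    S <- rowSums(y)
    if (phi <= 0) {
      ll <- ll + lgamma(S + 1) - rowSums(lgamma(y + 1)) - S * log(nk)
    } else {
      r <- 1 / phi
      ll <- ll + rowSums(lgamma(y + r)) + lgamma(nk * r) -
        lgamma(S + nk * r) - nk * lgamma(r) +
        lgamma(S + 1) - rowSums(lgamma(y + 1))
    }
  }
  ll
}

#' Estimate per-gene negative-binomial dispersions
#'
#' Conditional maximum likelihood on pseudo-counts equalized to a common
#' library size, evaluated on a log-spaced dispersion grid, with per-gene
#' empirical-Bayes moderation: each gene's conditional log-likelihood is
#' augmented by a weight times the average log-likelihood of the genes in
#' its abundance bin (a mean-dispersion trend), and the maximizing
#' dispersion is refined by parabolic interpolation. By default the
#' moderation weight is estimated from the data by parametric bootstrap:
#' per abundance bin, the spread of raw per-gene estimates around the trend
#' is compared with the sampling spread of estimates simulated at the trend
#' dispersion, and the shrinkage is set to the implied signal fraction
#' (collapsing to the trend when the data show no dispersion heterogeneity
#' beyond sampling noise). Genes whose pooled within-group variance does not
#' exceed their mean are assigned dispersion 0 (Poisson floor).
#'
#' @param cm a \code{\link{count_matrix}} (filtered).
#' @param factors optional TMM factors used to form effective library sizes.
#' @param prior_df prior degrees of freedom of the shrinkage; \code{NULL}
#'   (default) estimates it per abundance bin as described above.
#' @param n_bins abundance bins for the trend (default 20; at least 100 genes
#'   per bin).
#' @param grid_length dispersion grid resolution.
#' @param lib_sizes per-sample library sizes; default column sums. Override
#'   to normalize against another feature class from the same libraries.
#' @return numeric vector of per-gene dispersions, with attributes
#'   \code{common} (overall CML estimate) and \code{trend} (per-gene trend
#'   values).
#' @export
estimate_dispersion <- function(cm, factors = NULL, prior_df = NULL,
                                n_bins = 20, grid_length = 101,
                                lib_sizes = NULL) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  group <- if (inherits(cm, "count_matrix")) cm$samples$group else
    attr(cm, "group")
  tab <- table(group)
  if (length(tab) < 1 || max(tab) < 2) {
    stop("dispersion estimation requires replication ",
         "(at least two samples in some group)")
  }
  lib <- if (is.null(lib_sizes)) colSums(m) else lib_sizes
  if (is.null(factors)) factors <- rep(1, ncol(m))
  lib_eff <- lib * factors

  lg <- seq(log(1e-4), log(4), length.out = grid_length - 1)
  grid <- c(0, exp(lg))
  grid_ll <- function(ps) {
    L <- vapply(grid, function(ph) cond_loglik(ps, group, ph),
                numeric(nrow(m)))
    if (nrow(m) == 1) L <- matrix(L, nrow = 1)
    L
  }
  # first pass on linearly scaled counts fixes the common dispersion that
  # drives the quantile adjustment; the second pass estimates on the
  # properly equalized pseudo-counts
  ps <- pseudo_counts(m, lib_eff)
  L <- grid_ll(ps)
  if (max(abs(lib_eff / exp(mean(log(lib_eff))) - 1)) >= 1e-12) {
    common1 <- grid[which.max(colSums(L))]
    ps <- pseudo_counts(m, lib_eff, dispersion = common1)
    L <- grid_ll(ps)
  }

  # abundance bins for the mean-dispersion trend
  ab <- rowMeans(ps)
  n_bins <- max(1, min(n_bins, floor(nrow(m) / 100)))
  bin <- if (n_bins > 1) {
    cut(rank(ab, ties.method = "first"), breaks = n_bins, labels = FALSE)
  } else {
    rep(1L, nrow(m))
  }
  binmean <- rowsum(L, bin) / as.vector(table(bin))
  # smooth the binned prior likelihood across neighbouring abundance bins
  # so the trend varies slowly with abundance instead of tracking per-bin
  # estimation noise
  if (nrow(binmean) > 2) {
    half <- 2L
    sm <- binmean
    for (b in seq_len(nrow(binmean))) {
      win <- max(1, b - half):min(nrow(binmean), b + half)
      sm[b, ] <- colMeans(binmean[win, , drop = FALSE])
    }
    binmean <- sm
  }
  common_i <- which.max(colSums(L))
  df_resid <- length(group) - length(unique(group))
  trend_phi_bin <- grid[apply(binmean, 1, which.max)]

  if (!is.null(prior_df)) {
    prior_n_bin <- rep(prior_df / max(df_resid, 1), nrow(binmean))
  } else {
    # parametric bootstrap per bin: how much of the spread of raw per-gene
    # estimates around the trend is sampling noise at the trend dispersion?
    phi_raw <- grid[max.col(L, ties.method = "first")]
    group_sizes <- as.integer(table(group))
    prior_n_bin <- vapply(seq_len(nrow(binmean)), function(b) {
      idx <- which(bin == b)
      if (length(idx) < 10) return(500)
      mu_b <- exp(mean(log(rowMeans(ps[idx, , drop = FALSE]) + 0.5)))
      phi_b <- trend_phi_bin[b]
      nsim <- 200L
      ysim <- matrix(if (phi_b > 0) {
        stats::rnbinom(nsim * length(group), mu = mu_b, size = 1 / phi_b)
      } else {
        stats::rpois(nsim * length(group), mu_b)
      }, nsim, length(group))
      L0 <- vapply(grid, function(ph) cond_loglik(ysim, group, ph),
                   numeric(nsim))
      phi0 <- grid[max.col(L0, ties.method = "first")]
      var0 <- stats::var(log(phi0 + 0.05))
      var_obs <- stats::var(log(phi_raw[idx] + 0.05))
      if (!is.finite(var0) || !is.finite(var_obs)) return(500)
      # only loosen the shrinkage when the observed spread significantly
      # exceeds the sampling spread at the trend dispersion
      crit <- stats::qf(0.95, length(idx) - 1, nsim - 1)
      if (var0 <= 0 || var_obs <= var0 * crit) return(500)
      w <- var0 / var_obs   # fraction of spread that is sampling noise
      min(max(w / (1 - w + 1e-8), 0.05), 500)
    }, 0)
  }
  Lmod <- L + prior_n_bin[bin] * binmean[bin, , drop = FALSE]

  i <- max.col(Lmod, ties.method = "first")
  phi <- grid[i]
  # parabolic refinement on log-phi for interior maxima
  interior <- which(i > 2 & i < length(grid))
  if (length(interior)) {
    ii <- i[interior]
    x0 <- lg[ii - 2]; x1 <- lg[ii - 1]
    y0 <- Lmod[cbind(interior, ii - 1)]
    y1 <- Lmod[cbind(interior, ii)]
    y2 <- Lmod[cbind(interior, ii + 1)]
    denom <- y0 - 2 * y1 + y2
    ok <- is.finite(denom) & denom < 0
    xv <- x1 + 0.5 * (y0 - y2) / denom * (x1 - x0)
    xv <- pmin(pmax(xv, x0), lg[pmin(ii + 1, length(lg))])
    phi[interior[ok]] <- exp(xv[ok])
  }

  # Poisson floor for genes whose within-group variance is clearly
  # sub-Poisson (e.g. constant counts). The floor is applied only when the
  # variance falls significantly below the Poisson expectation: flooring
  # every gene with sample variance <= mean would override the shrinkage
  # for genes that hit a small variance by chance and hand them spuriously
  # small Poisson p-values downstream.
  ssq <- 0; mn <- 0; dfs <- 0
  for (k in unique(group)) {
    y <- ps[, group == k, drop = FALSE]
    if (ncol(y) > 1) {
      ssq <- ssq + apply(y, 1, stats::var) * (ncol(y) - 1)
      dfs <- dfs + (ncol(y) - 1)
    }
    mn <- mn + rowSums(y)
  }
  pool_var <- ssq / dfs
  pool_mean <- mn / length(group)
  sub_poisson <- dfs * pool_var / pmax(pool_mean, 1e-12) <=
    stats::qchisq(0.05, dfs)
  phi[sub_poisson] <- 0

  attr(phi, "common") <- grid[common_i]
  attr(phi, "trend") <- trend_phi_bin[bin]
  names(phi) <- rownames(m)
  phi
}

# two-sided exact conditional NB p-value for one gene.
# Conditional on the total of the two group sums, the first group's sum
# follows a negative hypergeometric law that depends only on the group sizes
# and the dispersion (binomial in the Poisson limit). The smaller tail is
# doubled and capped at 1.
exact_nb_p <- function(y1, y2, n1, n2, phi) {
  S <- y1 + y2
  if (S == 0) return(1)
  y <- 0:S
  if (phi <= 0) {
    lp <- stats::dbinom(y, S, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi
    r2 <- n2 / phi
    lp <- lchoose(y + r1 - 1, y) + lchoose(S - y + r2 - 1, S - y)
    lp <- lp - max(lp)
    lp <- lp - log(sum(exp(lp)))
  }
  p <- exp(lp)
  lower <- sum(p[y <= y1])
  upper <- sum(p[y >= y1])
  min(1, 2 * min(lower, upper))
}

#' Exact-style negative-binomial differential-expression test
#'
#' Per-gene two-sided test between two groups. Counts are first equalized to
#' a common effective library size (pseudo-counts); conditional on the total
#' of the two group sums, the first group's sum is negative hypergeometric
#' (binomial at dispersion 0), and the smaller conditional tail probability
#' is doubled and capped at 1. Log2 fold changes use a prior count of 0.125
#' per library.
#'
#' @param cm a \code{\link{count_matrix}} (filtered), with exactly two groups.
#' @param factors TMM factors from \code{\link{tmm_factors}}; default all 1.
#' @param dispersion per-gene dispersions from
#'   \code{\link{estimate_dispersion}} (recycled if scalar).
#' @param prior_count prior count per library for the fold change.
#' @param lib_sizes per-sample library sizes; default column sums. Exon and
#'   intron counts from the same libraries should share one set of effective
#'   library sizes so that normalization cancels in the delta statistic.
#' @return data frame (class \code{de_result}) with columns \code{gene_id},
#'   \code{log_fc} (second group vs first, i.e. knockout vs control when
#'   groups are named that way), \code{mean_cpm} (average log2 CPM),
#'   \code{p_value}, \code{fdr}, \code{direction}.
#' @export
nb_test <- function(cm, factors = NULL, dispersion = 0, prior_count = 0.125,
                    lib_sizes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  groups <- cm$samples$group
  glev <- unique(groups)
  if (length(glev) != 2) stop("nb_test requires exactly two groups")
  # control first when present
  if ("control" %in% glev) glev <- c("control", setdiff(glev, "control"))
  m <- cm$counts
  phi <- rep_len(dispersion, nrow(m))
  if (length(dispersion) > 1 && length(dispersion) != nrow(m)) {
    stop("dispersion length must match the number of genes")
  }
  lib <- if (is.null(lib_sizes)) colSums(m) else lib_sizes
  if (is.null(factors)) factors <- rep(1, ncol(m))
  phi_common <- attr(dispersion, "common")
  if (is.null(phi_common)) phi_common <- stats::median(phi)
  ps <- pseudo_counts(m, lib * factors, dispersion = phi_common)
  i1 <- groups == glev[1]
  i2 <- groups == glev[2]
  n1 <- sum(i1)
  n2 <- sum(i2)
  s1 <- rowSums(ps[, i1, drop = FALSE])
  s2 <- rowSums(ps[, i2, drop = FALSE])
  r1 <- round(s1)
  r2 <- round(s2)
  p <- vapply(seq_len(nrow(m)),
              function(g) exact_nb_p(r1[g], r2[g], n1, n2, phi[g]), 0)
  m1 <- s1 / n1
  m2 <- s2 / n2
  log_fc <- log2((m2 + prior_count) / (m1 + prior_count))
  common <- exp(mean(log(lib * factors)))
  mean_cpm <- log2(1e6 * (s1 + s2 + 2 * prior_count) /
                     ((n1 + n2) * common))
  out <- data.frame(gene_id = rownames(m), log_fc = log_fc,
                    mean_cpm = mean_cpm, p_value = p, fdr = bh_fdr(p),
                    direction = ifelse(log_fc >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment over the tested family.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]; NaN/NA is an error.
#' @return adjusted p-values of the same length.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values))) stop("p-values must be finite (no NA/NaN)")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Run the full differential-expression pipeline
#'
#' Filter, TMM-normalize, estimate dispersions, and test.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param cpm_min,min_samples expression-filter settings.
#' @param prior_df dispersion-shrinkage prior degrees of freedom
#'   (\code{NULL}: estimated from the data).
#' @return a \code{de_result} data frame (see \code{\link{nb_test}}).
#' @export
run_de <- function(cm, cpm_min = 1, min_samples = 3, prior_df = NULL) {
  f <- filter_expressed(cm, cpm_min, min_samples)
  fac <- tmm_factors(f)
  phi <- estimate_dispersion(f, factors = fac, prior_df = prior_df)
  nb_test(f, factors = fac, dispersion = phi)
}
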