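#' Smooth traces with a centred moving average
#'
#' @param ts a \code{\link{trace_set}}.
#' @param window odd number of samples (default 5); 1 is the identity. At the
#'   trace edges the window shrinks symmetrically.
#' @return the smoothed \code{trace_set}.
#' @export
smooth_traces <- function(ts, window = 5) {
  stopifnot(inherits(ts, "trace_set"))
  if (window < 1 || window > ncol(ts$F)) {
    stop("window must be between 1 and the trace length")
  }
  if (window %% 2 == 0) stop("window must be odd (centred average)")
  if (window == 1) return(ts)
  h <- (window - 1) / 2
  nt <- ncol(ts$F)
  sm <- ts$F
  cs <- cbind(0, t(apply(ts$F, 1, cumsum)))
  for (t in seq_len(nt)) {
    lo <- max(1, t - h)
    hi <- min(nt, t + h)
    # shrink symmetrically at the edges so the window stays centred
    half <- min(t - lo, hi - t)
    lo <- t - half
    hi <- t + half
    sm[, t] <- (cs[, hi + 1] - cs[, lo]) / (hi - lo + 1)
  }
  trace_set(ts$time_s, sm, ts$epochs, ts$coords)
}

#' Normalize traces to basal minimum fluorescence (F/F_min)
#'
#' Each cell's trace is divided by its minimum fluorescence within the basal
#' (low-glucose) epoch, so the basal minimum maps to 1 and traces become
#' comparable across cells and detector gains.
#'
#' @param ts a \code{\link{trace_set}}.
#' @param basal_epoch epoch name of the basal window (default \code{"3G"}).
#' @return the normalized \code{trace_set}.
#' @export
normalize_fmin <- function(ts, basal_epoch = "3G") {
  stopifnot(inherits(ts, "trace_set"))
  w <- epoch_window(ts, basal_epoch)
  fmin <- apply(ts$F[, w, drop = FALSE], 1, min)
  bad <- which(fmin <= 0)
  if (length(bad) > 0) {
    stop("non-positive basal minimum for cell ", rownames(ts$F)[bad[1]])
  }
  trace_set(ts$time_s, ts$F / fmin, ts$epochs, ts$coords)
}

#' All-pairs Pearson correlation matrix
#'
#' @param ts a \code{\link{trace_set}} (typically smoothed and normalized).
#' @param epoch optional epoch name; correlations are then computed within
#'   that window only.
#' @return symmetric cell-by-cell correlation matrix with \code{NA} on the
#'   diagonal (autocorrelation excluded from all summaries). Zero-variance
#'   cells yield \code{NA} rows/columns with a warning.
#' @export
pearson_matrix <- function(ts, epoch = NULL) {
  stopifnot(inherits(ts, "trace_set"))
  F <- ts$F
  if (!is.null(epoch)) F <- F[, epoch_window(ts, epoch), drop = FALSE]
  if (nrow(F) < 2 || ncol(F) < 3) {
    stop("need at least 2 cells and 3 timepoints")
  }
  v <- apply(F, 1, stats::var)
  if (any(v == 0)) {
    warning("zero-variance cell(s) excluded: ",
            paste(rownames(F)[v == 0], collapse = ", "))
  }
  R <- suppressWarnings(stats::cor(t(F)))
  R[v == 0, ] <- NA
  R[, v == 0] <- NA
  diag(R) <- NA
  R
}

#' Permutation significance of cell-pair correlations
#'
#' The null preserves each trace's autocorrelation: for every pair, one trace
#' is circularly time-shifted by uniformly random offsets of at least
#' \code{min_shift} samples, and the two-sided empirical p-value (with +1
#' correction) compares the observed |r| with the shifted-null |r|. BH
#' correction is applied across pairs.
#'
#' @param ts a \code{\link{trace_set}} (smoothed, normalized).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param alpha BH significance level (default 0.05).
#' @param min_shift minimum circular shift in samples (default 10).
#' @param epoch optional epoch restriction.
#' @param seed integer seed.
#' @return list of class \code{connectivity_result}: \code{R} (correlations),
#'   \code{p_perm}, \code{significant} (BH mask), \code{pct_connected}
#'   (per-cell percentage of significant partners),
#'   \code{mean_pct_connected}, \code{alpha}, \code{n_perm}.
#' @export
permutation_significance <- function(ts, n_perm = 1000, alpha = 0.05,
                                     min_shift = 10, epoch = NULL,
                                     seed = 1L) {
  stopifnot(inherits(ts, "trace_set"))
  if (n_perm < 100) stop("n_perm must be at least 100")
  F <- ts$F
  if (!is.null(epoch)) F <- F[, epoch_window(ts, epoch), drop = FALSE]
  n <- nrow(F)
  n_t <- ncol(F)
  if (n_t < 2 * min_shift + 1) {
    stop("traces too short for the minimum circular shift")
  }
  set.seed(seed)
  # population-standardize so that circular cross-products are correlations
  Z <- (F - rowMeans(F)) / sqrt(pmax(rowMeans(F^2) - rowMeans(F)^2, 0))
  sdz <- sqrt(rowMeans(F^2) - rowMeans(F)^2)
  zero_var <- sdz == 0
  FZ <- t(apply(Z, 1, function(x) stats::fft(x)))

  R <- matrix(NA_real_, n, n, dimnames = list(rownames(F), rownames(F)))
  P <- matrix(NA_real_, n, n, dimnames = dimnames(R))
  shift_pool <- min_shift:(n_t - min_shift)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (zero_var[i] || zero_var[j]) next
      # r at every circular lag via the cross-spectrum
      r_lags <- Re(stats::fft(FZ[i, ] * Conj(FZ[j, ]),
                              inverse = TRUE)) / n_t^2
      r_obs <- r_lags[1]
      shifts <- sample(shift_pool, n_perm, replace = TRUE)
      r_null <- r_lags[shifts + 1]
      p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (n_perm + 1)
      R[i, j] <- R[j, i] <- r_obs
      P[i, j] <- P[j, i] <- p
    }
  }
  ut <- upper.tri(R)
  pv <- P[ut]
  sig <- matrix(FALSE, n, n, dimnames = dimnames(R))
  ok <- !is.na(pv)
  adj <- rep(NA_real_, length(pv))
  adj[ok] <- bh_fdr(pv[ok])
  sigv <- !is.na(adj) & adj < alpha
  sig[ut] <- sigv
  sig <- sig | t(sig)
  pct <- 100 * rowSums(sig) / (n - 1)
  structure(list(R = R, p_perm = P, significant = sig,
                 pct_connected = pct,
                 mean_pct_connected = mean(pct),
                 alpha = alpha, n_perm = n_perm),
            class = "connectivity_result")
}

#' Default correlation-strength colour bins
#'
#' R of 0.1-0.25 is drawn blue, 0.26-0.5 green, 0.51-0.75 yellow and
#' 0.76-1.0 red; pairs below 0.1 are not drawn.
#'
#' @export
default_bins <- function() {
  data.frame(bin = c("blue", "green", "yellow", "red"),
             lower = c(0.10, 0.25, 0.50, 0.75),
             upper = c(0.25, 0.50, 0.75, 1.00),
             stringsAsFactors = FALSE)
}

#' Assign connectivity edges to colour bins
#'
#' @param R correlation matrix (e.g. from \code{\link{pearson_matrix}}).
#' @param thresholds bin table with columns \code{bin}, \code{lower},
#'   \code{upper}; adjacent intervals \code{(lower, upper]} with the lowest
#'   bound inclusive. Default \code{\link{default_bins}()}.
#' @param significant optional boolean mask; only significant pairs become
#'   edges.
#' @return data frame of edges: \code{cell_i}, \code{cell_j}, \code{r},
#'   \code{bin}. Pairs below the lowest bound are omitted.
#' @export
bin_edges <- function(R, thresholds = default_bins(), significant = NULL) {
  o <- order(thresholds$lower)
  thresholds <- thresholds[o, , drop = FALSE]
  if (any(thresholds$lower >= thresholds$upper)) {
    stop("each bin needs lower < upper")
  }
  if (nrow(thresholds) > 1 &&
      any(thresholds$lower[-1] < thresholds$upper[-nrow(thresholds)] - 1e-9)) {
    stop("bins must not overlap")
  }
  ut <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[ut]
  keep <- !is.na(r)
  if (!is.null(significant)) keep <- keep & significant[ut]
  ut <- ut[keep, , drop = FALSE]
  r <- r[keep]
  assign_bin <- function(x) {
    if (x >= thresholds$lower[1] - 1e-12 && x <= thresholds$upper[1]) {
      return(thresholds$bin[1])
    }
    for (k in seq_len(nrow(thresholds))[-1]) {
      if (x > thresholds$lower[k] && x <= thresholds$upper[k]) {
        return(thresholds$bin[k])
      }
    }
    NA_character_
  }
  bins <- vapply(r, assign_bin, "")
  cells <- rownames(R)
  out <- data.frame(cell_i = cells[ut[, 1]], cell_j = cells[ut[, 2]],
                    r = r, bin = bins, stringsAsFactors = FALSE)
  out <- out[!is.na(out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Area under the curve of the islet-average response within an epoch
#'
#' The cell-averaged (normalized) trace has a group-specific baseline
#' subtracted and is integrated by the trapezoid rule over the epoch.
#' Negative excursions below baseline are included unless \code{clamp} is
#' set.
#'
#' @param ts a normalized \code{\link{trace_set}} (one islet).
#' @param epoch epoch name.
#' @param baseline group-specific baseline (e.g. 0.95 for control, 1.03 for
#'   knockout at high glucose).
#' @param clamp drop the signal below baseline before integrating
#'   (default FALSE).
#' @return list of class \code{auc_result}: \code{auc} (normalized-F seconds),
#'   \code{baseline}, \code{epoch}.
#' @export
epoch_auc <- function(ts, epoch, baseline, clamp = FALSE) {
  stopifnot(inherits(ts, "trace_set"))
  if (!is.finite(baseline)) stop("baseline must be finite")
  w <- epoch_window(ts, epoch)
  y <- colMeans(ts$F[, w, drop = FALSE]) - baseline
  if (clamp) y <- pmax(y, 0)
  structure(list(auc = trapezoid(ts$time_s[w], y),
                 baseline = baseline, epoch = epoch),
            class = "auc_result")
}
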