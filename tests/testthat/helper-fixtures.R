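# small in-code fixtures shared across test files

# count_matrix from a bare matrix, default 3v3 control/knockout
make_cm <- function(m, groups = NULL, feature_class = "exon") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) {
    half <- ncol(m) / 2
    colnames(m) <- c(sprintf("ctl_%d", seq_len(half)),
                     sprintf("ko_%d", seq_len(ncol(m) - half)))
  }
  if (is.null(groups)) {
    groups <- ifelse(grepl("^ctl", colnames(m)), "control", "knockout")
    names(groups) <- colnames(m)
  }
  count_matrix(m, groups, feature_class)
}

# trace_set with a single basal epoch spanning the whole recording
make_ts <- function(F, dt = 1, epoch_name = "3G") {
  nt <- ncol(F)
  time_s <- seq(0, by = dt, length.out = nt)
  trace_set(time_s, F,
            data.frame(name = epoch_name, start_s = 0,
                       end_s = max(time_s)))
}

# independent brute-force two-sided conditional binomial p-value:
# enumerate every split of the total at fixed sum via Poisson products
enum_conditional_p <- function(y1, y2, n1, n2) {
  S <- y1 + y2
  y <- 0:S
  # P(Y1 = y | S) from products of Poisson masses at an arbitrary mean
  mu <- 1
  lw <- stats::dpois(y, n1 * mu, log = TRUE) +
    stats::dpois(S - y, n2 * mu, log = TRUE)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  lower <- sum(w[y <= y1])
  upper <- sum(w[y >= y1])
  min(1, 2 * min(lower, upper))
}

# independent brute-force running sum for the unweighted enrichment statistic
ks_oracle <- function(n_total, hit_positions) {
  n_set <- length(hit_positions)
  rs <- 0
  best <- 0
  for (i in seq_len(n_total)) {
    rs <- rs + if (i %in% hit_positions) 1 / n_set else -1 / (n_total - n_set)
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# hand step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
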