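#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, \code{dCt = Ct_target - Ct_reference}; \code{ddCt} subtracts
#' the calibrator group's mean dCt, and relative expression is
#' \code{2^(-ddCt)}, so the calibrator group's geometric-mean expression is 1.
#' Amplification efficiency is fixed at 2 per cycle (plain delta-delta-Ct);
#' an efficiency-corrected variant is available via \code{efficiency}.
#'
#' @param ct data frame with columns \code{sample}, \code{group},
#'   \code{target_ct}, \code{reference_ct} (reference: e.g. Gapdh).
#' @param calibrator_group group label used as calibrator.
#' @param efficiency amplification factor per cycle (default 2).
#' @return the input with added columns \code{dct}, \code{ddct},
#'   \code{rel_expr}.
#' @export
ddct <- function(ct, calibrator_group, efficiency = 2) {
  need <- c("sample", "group", "target_ct", "reference_ct")
  if (!all(need %in% names(ct))) {
    stop("ct table must have columns ", paste(need, collapse = ", "))
  }
  miss <- which(!is.finite(ct$reference_ct))
  if (length(miss) > 0) {
    stop("missing reference Ct for sample ", ct$sample[miss[1]])
  }
  if (!any(ct$group == calibrator_group)) {
    stop("calibrator group '", calibrator_group, "' is empty")
  }
  ct$dct <- ct$target_ct - ct$reference_ct
  cal_mean <- mean(ct$dct[ct$group == calibrator_group])
  ct$ddct <- ct$dct - cal_mean
  ct$rel_expr <- efficiency^(-ct$ddct)
  ct
}

#' Normalize a decay time course to its t = 0 level
#'
#' Each replicate series is divided by its own value at time 0 and scaled to
#' percent, so every replicate starts at exactly 100.
#'
#' @param raw data frame with columns \code{gene}, \code{genotype},
#'   \code{replicate}, \code{time_hr}, \code{value} (relative expression,
#'   e.g. reference-normalized qPCR).
#' @return a \code{decay_course} data frame with
#'   \code{relative_abundance} in percent of t = 0.
#' @export
normalize_decay <- function(raw) {
  need <- c("gene", "genotype", "replicate", "time_hr", "value")
  if (!all(need %in% names(raw))) {
    stop("decay table must have columns ", paste(need, collapse = ", "))
  }
  key <- interaction(raw$gene, raw$genotype, raw$replicate, drop = TRUE)
  out <- do.call(rbind, lapply(split(raw, key), function(d) {
    i0 <- which(d$time_hr == 0)
    if (length(i0) != 1) {
      stop("each replicate series needs exactly one t = 0 measurement")
    }
    if (d$value[i0] <= 0) stop("t = 0 value must be positive")
    d$relative_abundance <- 100 * d$value / d$value[i0]
    d$value <- NULL
    d
  }))
  rownames(out) <- NULL
  class(out) <- c("decay_course", "data.frame")
  out
}

# per-replicate log-linear slopes (log2 percent vs hours, through the origin;
# the t = 0 point is fixed at 100 by normalization and carries no information)
replicate_slopes <- function(course) {
  key <- interaction(course$genotype, course$replicate, drop = TRUE)
  vapply(split(course, key), function(d) {
    d <- d[d$time_hr > 0, , drop = FALSE]
    y <- log2(d$relative_abundance / 100)
    sum(d$time_hr * y) / sum(d$time_hr^2)
  }, 0)
}

#' Fit a first-order decay half-life
#'
#' Least squares of \code{log2(relative_abundance / 100)} on time through the
#' origin (the t = 0 level is 100 by construction). The half-life is
#' \code{-1 / slope} hours and the decay rate \code{k = -slope * ln(2)} per
#' hour, so \code{t_half * k = ln(2)} exactly. With two or more replicates
#' the confidence interval uses the between-replicate spread of per-replicate
#' slopes (t distribution, replicates - 1 df); with a single series it falls
#' back to the residual standard error. A non-decaying fit is flagged stable
#' with unbounded half-life.
#'
#' @param course a \code{decay_course} for a single gene and genotype.
#' @param conf confidence level (default 0.95).
#' @return list of class \code{half_life_fit}: \code{slope_log2_per_hr},
#'   \code{k_per_hr}, \code{t_half_hr}, \code{ci_hr} (half-life interval),
#'   \code{r_squared}, \code{stable}, \code{n_replicates}.
#' @export
fit_half_life <- function(course, conf = 0.95) {
  if (length(unique(course$gene)) > 1 || length(unique(course$genotype)) > 1) {
    stop("fit one gene and one genotype at a time")
  }
  if (length(unique(course$time_hr)) < 3 || !any(course$time_hr == 0)) {
    stop("need at least three timepoints including 0")
  }
  if (any(course$relative_abundance <= 0)) {
    stop("relative abundances must be positive")
  }
  d <- course[course$time_hr > 0, , drop = FALSE]
  y <- log2(d$relative_abundance / 100)
  x <- d$time_hr
  slope <- sum(x * y) / sum(x^2)
  res <- y - slope * x
  r2 <- if (sum(y^2) > 0) 1 - sum(res^2) / sum(y^2) else 1

  slopes <- replicate_slopes(course)
  m <- length(slopes)
  if (m >= 2) {
    se <- stats::sd(slopes) / sqrt(m)
    df <- m - 1
    slope <- mean(slopes)  # equals the pooled slope for balanced series
  } else {
    df <- max(length(y) - 1, 1)
    se <- sqrt(sum(res^2) / df / sum(x^2))
  }
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  lo <- slope - tq * se
  hi <- slope + tq * se
  stable <- slope >= 0
  inv <- function(s) if (s < 0) -1 / s else Inf
  ci <- sort(c(inv(hi), inv(lo)))
  structure(list(slope_log2_per_hr = slope,
                 k_per_hr = -slope * log(2),
                 t_half_hr = inv(slope),
                 ci_hr = ci,
                 r_squared = r2,
                 stable = stable,
                 n_replicates = m),
            class = "half_life_fit")
}

#' @export
print.half_life_fit <- function(x, ...) {
  cat(sprintf("half-life %.3g h (95%% CI %.3g-%.3g), k = %.3g /h, R2 = %.3f%s\n",
              x$t_half_hr, x$ci_hr[1], x$ci_hr[2], x$k_per_hr, x$r_squared,
              if (x$stable) " [stable: no decay detected]" else ""))
  invisible(x)
}

#' Compare decay between genotypes (stabilization test)
#'
#' Genotype-by-time interaction on the log scale: per-replicate log2 decay
#' slopes are compared between the two genotypes with an equal-variance
#' two-sided t test. Direction is \code{"stabilized"} when the knockout (or
#' second) genotype decays more slowly.
#'
#' @param control,ko \code{decay_course} objects for the two genotypes with
#'   the same timepoints and at least two replicates each.
#' @return list: \code{p}, \code{direction} (\code{"stabilized"},
#'   \code{"destabilized"} or \code{"none"}), \code{slope_control},
#'   \code{slope_ko}, \code{t_half_control}, \code{t_half_ko}.
#' @export
compare_decay <- function(control, ko) {
  if (!setequal(unique(control$time_hr), unique(ko$time_hr))) {
    stop("the two courses must share timepoints")
  }
  s1 <- replicate_slopes(control)
  s2 <- replicate_slopes(ko)
  if (length(s1) < 2 || length(s2) < 2) {
    stop("at least two replicates per genotype are required")
  }
  if (stats::sd(c(s1 - mean(s1), s2 - mean(s2))) == 0) {
    p <- if (mean(s1) == mean(s2)) 1 else 0
  } else {
    p <- stats::t.test(s1, s2, var.equal = TRUE)$p.value
  }
  diff <- mean(s2) - mean(s1)
  direction <- if (mean(s1) == mean(s2)) "none" else
    if (diff > 0) "stabilized" else "destabilized"
  inv <- function(s) if (s < 0) -1 / s else Inf
  list(p = p, direction = direction,
       slope_control = mean(s1), slope_ko = mean(s2),
       t_half_control = inv(mean(s1)), t_half_ko = inv(mean(s2)))
}

#' RNA-immunoprecipitation enrichment
#'
#' Recovered mRNA is quantified as percent of input, with the input Ct
#' adjusted for the fraction of lysate it represents
#' (\code{Ct_input - log2(1 / input_fraction)}), and the antibody pulldown is
#' expressed as fold change over the IgG control.
#'
#' @param input_ct,igg_ct,ab_ct Ct values (vectors match by position, e.g.
#'   one entry per gene).
#' @param input_fraction fraction of lysate used as input, in (0, 1].
#' @return data frame with \code{pct_input_igg}, \code{pct_input_ab},
#'   \code{fold_over_igg}.
#' @export
rip_enrichment <- function(input_ct, igg_ct, ab_ct, input_fraction = 0.1) {
  if (input_fraction <= 0 || input_fraction > 1) {
    stop("input_fraction must be in (0, 1]")
  }
  adj <- input_ct - log2(1 / input_fraction)
  pct_igg <- 100 * 2^(adj - igg_ct)
  pct_ab <- 100 * 2^(adj - ab_ct)
  data.frame(pct_input_igg = pct_igg, pct_input_ab = pct_ab,
             fold_over_igg = pct_ab / pct_igg)
}

#' Beta-cell mass from morphometry
#'
#' Insulin-positive area divided by total pancreatic area, multiplied by
#' pancreas weight.
#'
#' @param insulin_area,total_area areas in the same (arbitrary) units,
#'   \code{0 <= insulin_area <= total_area}.
#' @param pancreas_weight_mg pancreas weight in milligrams.
#' @return mass in milligrams.
#' @export
beta_cell_mass <- function(insulin_area, total_area, pancreas_weight_mg) {
  if (any(total_area <= 0)) stop("total area must be positive")
  if (any(insulin_area < 0 | insulin_area > total_area)) {
    stop("insulin area must lie between 0 and the total area")
  }
  if (any(pancreas_weight_mg <= 0)) stop("pancreas weight must be positive")
  (insulin_area / total_area) * pancreas_weight_mg
}

#' Two-group comparison utilities
#'
#' Two-tailed Student's t test (equal variance) or Mann-Whitney test, the two
#' procedures used for summary-table group comparisons.
#'
#' @param x,y numeric vectors.
#' @param method \code{"t"} or \code{"mann-whitney"}.
#' @return list with \code{p} and \code{method}.
#' @export
group_compare <- function(x, y, method = c("t", "mann-whitney")) {
  method <- match.arg(method)
  p <- if (method == "t") {
    stats::t.test(x, y, var.equal = TRUE)$p.value
  } else {
    stats::wilcox.test(x, y, exact = FALSE)$p.value
  }
  list(p = p, method = method)
}
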