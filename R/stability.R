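#' The delta-exon minus delta-intron stability statistic
#'
#' The change in mRNA half-life is estimated as the difference between the
#' log2 fold change in exonic reads (steady-state abundance) and the log2
#' fold change in intronic reads (transcription): genes whose exonic reads
#' rise more than their intronic reads are inferred to be stabilized.
#'
#' @param exon_de,intron_de \code{de_result} tables from \code{\link{nb_test}}
#'   computed on the same samples. Genes are matched by identifier; genes
#'   present in only one table (e.g. lacking intron signal after filtering)
#'   are excluded with a message.
#' @return data frame (class \code{stability_records}) with columns
#'   \code{gene_id}, \code{exon_logfc}, \code{intron_logfc}, \code{delta}.
#' @export
delta_exon_intron <- function(exon_de, intron_de) {
  shared <- intersect(exon_de$gene_id, intron_de$gene_id)
  if (length(shared) == 0) {
    stop("no genes shared between the exon and intron tables")
  }
  dropped <- length(union(exon_de$gene_id, intron_de$gene_id)) - length(shared)
  if (dropped > 0) {
    message(dropped,
            " gene(s) present in only one feature class were excluded")
  }
  e <- exon_de[match(shared, exon_de$gene_id), ]
  i <- intron_de[match(shared, intron_de$gene_id), ]
  out <- data.frame(gene_id = shared,
                    exon_logfc = e$log_fc,
                    intron_logfc = i$log_fc,
                    delta = e$log_fc - i$log_fc,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("stability_records", "data.frame")
  out
}

#' Per-gene test of differential stability (exon x group interaction)
#'
#' Tests, for each gene, whether the exonic fold change differs from the
#' intronic fold change. The negative-binomial log-linear model with
#' feature-class-by-group interaction and per-sample nuisance effects is fit
#' in its equivalent conditional form: given each sample's exon + intron
#' total, the exon count is binomial, and the interaction is the group effect
#' on the log-odds of exon vs intron. A likelihood-ratio chi-square (1 df)
#' gives the two-sided p-value; per-sample effects (library size, shared
#' biological variation in transcription) cancel in the within-sample ratio.
#'
#' @param exon_cm,intron_cm filtered \code{\link{count_matrix}} objects on the
#'   same samples. Genes are matched by id; unmatched genes are excluded with
#'   a message.
#' @param overdispersion \code{"none"} (binomial LRT; default) or
#'   \code{"quasi"}: the LRT statistic is divided by a global quasi-likelihood
#'   scale (median Pearson dispersion across genes, floored at 1).
#' @return data frame with columns \code{gene_id}, \code{p_interaction},
#'   \code{fdr} (BH across tested genes).
#' @export
test_interaction <- function(exon_cm, intron_cm,
                             overdispersion = c("none", "quasi")) {
  overdispersion <- match.arg(overdispersion)
  stopifnot(inherits(exon_cm, "count_matrix"),
            inherits(intron_cm, "count_matrix"))
  if (!identical(exon_cm$samples$sample, intron_cm$samples$sample)) {
    stop("exon and intron matrices must cover the same samples")
  }
  shared <- intersect(exon_cm$gene_ids, intron_cm$gene_ids)
  if (length(shared) == 0) stop("no genes shared between feature classes")
  dropped <- length(union(exon_cm$gene_ids, intron_cm$gene_ids)) -
    length(shared)
  if (dropped > 0) {
    message(dropped, " gene(s) absent from one feature class were excluded")
  }
  E <- exon_cm$counts[shared, , drop = FALSE]
  I <- intron_cm$counts[shared, , drop = FALSE]
  gf <- factor(exon_cm$samples$group)
  x1 <- stats::model.matrix(~gf)

  p <- numeric(length(shared))
  scale_num <- numeric(length(shared))
  for (g in seq_along(shared)) {
    e <- E[g, ]
    i <- I[g, ]
    tot <- e + i
    if (all(tot == 0)) {
      p[g] <- NA_real_
      next
    }
    f1 <- suppressWarnings(
      stats::glm.fit(x1, cbind(e, i), family = stats::binomial()))
    f0 <- suppressWarnings(
      stats::glm.fit(matrix(1, length(e), 1), cbind(e, i),
                     family = stats::binomial()))
    lrt <- f0$deviance - f1$deviance
    if (overdispersion == "quasi") {
      mu <- f1$fitted.values
      pr <- (e / pmax(tot, 1) - mu) * sqrt(pmax(tot, 1)) /
        sqrt(pmax(mu * (1 - mu), 1e-12))
      scale_num[g] <- sum(pr[tot > 0]^2) / max(1, sum(tot > 0) - ncol(x1))
    }
    p[g] <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  }
  if (overdispersion == "quasi") {
    s <- max(1, stats::median(scale_num, na.rm = TRUE))
    lrt_q <- stats::qchisq(p, 1, lower.tail = FALSE) / s
    p <- stats::pchisq(lrt_q, 1, lower.tail = FALSE)
  }
  ok <- !is.na(p)
  fdr <- rep(NA_real_, length(p))
  fdr[ok] <- bh_fdr(p[ok])
  data.frame(gene_id = shared, p_interaction = p, fdr = fdr,
             stringsAsFactors = FALSE)
}

#' Classify genes by stability and expression change
#'
#' A gene is \emph{stabilized} when its delta statistic is positive and the
#' interaction FDR is below \code{fdr_alpha}; \emph{stabilized_up} (a
#' deadenylase target candidate) additionally requires significant exonic
#' upregulation; \emph{destabilized} mirrors stabilized with negative delta;
#' \emph{transcription_driven} covers genes differentially expressed without
#' a stability change; everything else is \emph{unchanged}.
#'
#' @param records \code{stability_records} from \code{\link{delta_exon_intron}}.
#' @param interaction result of \code{\link{test_interaction}}.
#' @param exon_de exon-level \code{de_result}.
#' @param fdr_alpha significance level in (0, 1); default 0.05.
#' @return list with \code{records} (input plus columns \code{p_interaction},
#'   \code{fdr}, \code{class}) and \code{summary}: \code{n_stabilized},
#'   \code{n_stabilized_and_up}, \code{n_stabilized_not_up},
#'   \code{fraction_up}.
#' @export
classify_targets <- function(records, interaction, exon_de,
                             fdr_alpha = 0.05) {
  if (!(fdr_alpha > 0 && fdr_alpha < 1)) stop("fdr_alpha must be in (0, 1)")
  r <- merge(records, interaction, by = "gene_id", sort = FALSE)
  ei <- exon_de[match(r$gene_id, exon_de$gene_id), ]
  up <- !is.na(ei$fdr) & ei$fdr < fdr_alpha & ei$log_fc > 0
  de_sig <- !is.na(ei$fdr) & ei$fdr < fdr_alpha
  stab <- !is.na(r$fdr) & r$fdr < fdr_alpha & r$delta > 0
  destab <- !is.na(r$fdr) & r$fdr < fdr_alpha & r$delta < 0
  cls <- rep("unchanged", nrow(r))
  cls[de_sig] <- "transcription_driven"
  cls[destab] <- "destabilized"
  cls[stab & up] <- "stabilized_up"
  cls[stab & !up] <- "stabilized_not_up"
  r$class <- cls
  n_stab <- sum(stab)
  n_up <- sum(stab & up)
  if (n_stab == 0) {
    warning("no stabilized genes; fraction_up reported as 0")
  }
  summary <- list(n_stabilized = n_stab,
                  n_stabilized_and_up = n_up,
                  n_stabilized_not_up = n_stab - n_up,
                  fraction_up = if (n_stab > 0) n_up / n_stab else 0)
  list(records = r, summary = summary)
}

#' Intersection with a reference gene list
#'
#' Case-normalized, deterministic (sorted) intersection, e.g. of stabilized
#' and upregulated genes with genes upregulated in a diabetic-islet dataset.
#'
#' @param target_genes,reference_up_genes character vectors of identifiers.
#' @return list with \code{genes} (sorted intersection) and \code{n}.
#' @export
overlap_with_reference <- function(target_genes, reference_up_genes) {
  a <- unique(toupper(target_genes))
  b <- unique(toupper(reference_up_genes))
  g <- sort(intersect(a, b))
  list(genes = g, n = length(g))
}

#' End-to-end stability analysis from exon and intron counts
#'
#' Filters both matrices, normalizes, runs the differential-expression test
#' per feature class, forms the delta statistic, tests the interaction, and
#' classifies genes.
#'
#' @param exon_cm,intron_cm \code{\link{count_matrix}} objects on the same
#'   samples.
#' @param fdr_alpha significance level (default 0.05).
#' @param cpm_min,min_samples expression-filter settings applied to each
#'   feature class.
#' @param prior_df dispersion-shrinkage prior degrees of freedom (NULL: data-driven).
#' @return list with \code{records}, \code{summary} (see
#'   \code{\link{classify_targets}}), \code{exon_de}, \code{intron_de}.
#' @export
analyze_stability <- function(exon_cm, intron_cm, fdr_alpha = 0.05,
                              cpm_min = 1, min_samples = 3, prior_df = NULL) {
  ef <- filter_expressed(exon_cm, cpm_min, min_samples)
  if_ <- filter_expressed(intron_cm, cpm_min, min_samples)
  # exon and intron reads come from the same library, so both feature
  # classes share one set of per-sample effective library sizes (exonic
  # reads dominate and track depth); any residual normalization bias then
  # cancels exactly in delta = exon logFC - intron logFC
  fac_e <- tmm_factors(ef)
  eff_lib <- colSums(ef$counts) * fac_e
  exon_de <- nb_test(ef, factors = fac_e,
                     dispersion = estimate_dispersion(ef, factors = fac_e,
                                                      prior_df = prior_df))
  intron_de <- nb_test(if_, lib_sizes = eff_lib,
                       dispersion = estimate_dispersion(
                         if_, prior_df = prior_df, lib_sizes = eff_lib))
  records <- suppressMessages(delta_exon_intron(exon_de, intron_de))
  shared <- records$gene_id
  sub <- function(cm, ids) {
    count_matrix(cm$counts[ids, , drop = FALSE],
                 stats::setNames(cm$samples$group, cm$samples$sample),
                 cm$feature_class)
  }
  inter <- suppressMessages(
    test_interaction(sub(ef, shared), sub(if_, shared)))
  cl <- classify_targets(records, inter, exon_de, fdr_alpha)
  c(cl, list(exon_de = exon_de, intron_de = intron_de))
}
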