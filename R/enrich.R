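#' Rank genes for enrichment analysis
#'
#' Default ranking metric: signed log2 fold change, ties broken by p-value
#' (smaller first) and then lexicographic gene id.
#'
#' @param de a \code{de_result} data frame.
#' @return named numeric vector of metrics, sorted in decreasing order.
#' @export
rank_genes <- function(de) {
  o <- order(-de$log_fc, de$p_value, de$gene_id)
  stats::setNames(de$log_fc[o], de$gene_id[o])
}

#' Gene-set enrichment score (weighted Kolmogorov-Smirnov running sum)
#'
#' Walking down the ranked list, the running sum rises by
#' \code{|metric|^weight_p / sum over set of |metric|^weight_p} at each set
#' gene (equal steps when \code{weight_p = 0}) and falls by \code{1 / (N - n)}
#' otherwise. The enrichment score is the running sum's maximum deviation
#' from zero, signed; the leading edge contains the set genes up to (or, for
#' negative scores, after) the extremum.
#'
#' @param ranking named numeric vector of metrics (names = gene ids), sorted
#'   in decreasing order (see \code{\link{rank_genes}}).
#' @param set a \code{\link{gene_set}} or character vector of gene ids.
#' @param weight_p metric weighting exponent (default 1; 0 = classic
#'   unweighted statistic).
#' @return list of class \code{enrichment_result}: \code{es},
#'   \code{running_sum}, \code{leading_edge}, \code{n_set_in_ranking}.
#' @export
gsea_es <- function(ranking, set, weight_p = 1) {
  genes <- names(ranking)
  if (is.null(genes) || anyDuplicated(genes)) {
    stop("ranking must be a named vector with unique gene ids")
  }
  if (any(!is.finite(ranking))) stop("ranking metric must be finite")
  set_genes <- if (inherits(set, "gene_set")) set$genes else unique(set)
  hit <- genes %in% set_genes
  n_set <- sum(hit)
  if (n_set == 0) stop("no gene of the set appears in the ranking")
  N <- length(genes)
  if (n_set == N) {
    stop("the set covers the entire ranking; the score is undefined")
  }
  w <- abs(ranking)^weight_p
  denom <- sum(w[hit])
  inc <- ifelse(hit,
                if (denom > 0) w / denom else 1 / n_set,
                -1 / (N - n_set))
  if (denom == 0) inc[hit] <- 1 / n_set  # all-zero metrics: equal steps
  rs <- cumsum(inc)
  i_ext <- which.max(abs(rs))
  es <- rs[i_ext]
  leading <- if (es >= 0) {
    genes[seq_len(i_ext)][hit[seq_len(i_ext)]]
  } else {
    genes[i_ext:N][hit[i_ext:N]]
  }
  structure(list(es = es, running_sum = rs, leading_edge = leading,
                 n_set_in_ranking = n_set),
            class = "enrichment_result")
}

#' Permutation p-value for an enrichment score
#'
#' Gene-permutation null: scores of random gene sets of the same size drawn
#' from the ranked universe. Two-sided empirical p with +1 correction,
#' \code{p = (1 + #(|ES_null| >= |ES|)) / (n_perm + 1)}.
#'
#' @inheritParams gsea_es
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @return list: \code{es}, \code{p_perm}, \code{n_perm}.
#' @export
gsea_permutation_p <- function(ranking, set, n_perm = 1000, weight_p = 1,
                               seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  obs <- gsea_es(ranking, set, weight_p)
  n_set <- obs$n_set_in_ranking
  N <- length(ranking)
  if (n_set >= N) stop("set size must be smaller than the ranking")
  set.seed(seed)
  genes <- names(ranking)
  null_es <- vapply(seq_len(n_perm), function(k) {
    gsea_es(ranking, sample(genes, n_set), weight_p)$es
  }, 0)
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
  list(es = obs$es, p_perm = p, n_perm = n_perm)
}

#' Correlate transcriptome and proteome fold changes
#'
#' Pearson correlation of matched gene and protein log2 fold changes.
#'
#' @param gene_logfc data frame with columns \code{gene_id}, \code{log_fc}.
#' @param protein_logfc data frame with columns \code{protein_id},
#'   \code{log_fc}.
#' @param id_map optional data frame \code{gene_id}, \code{protein_id};
#'   when absent, protein ids are matched to gene ids directly
#'   (case-insensitively).
#' @return list of class \code{integration_result}: \code{r},
#'   \code{r_squared}, \code{p}, \code{n_matched}.
#' @export
correlate_omics <- function(gene_logfc, protein_logfc, id_map = NULL) {
  g <- gene_logfc
  p <- protein_logfc
  if (is.null(id_map)) {
    id_map <- data.frame(gene_id = g$gene_id,
                         protein_id = toupper(g$gene_id),
                         stringsAsFactors = FALSE)
    p$protein_id <- toupper(p$protein_id)
  }
  m <- merge(merge(id_map, g, by = "gene_id"), p, by = "protein_id",
             suffixes = c("_gene", "_protein"))
  n <- nrow(m)
  if (n < 3) stop("fewer than 3 matched gene-protein pairs")
  unmatched <- nrow(g) - n
  if (unmatched > 0) message(unmatched, " gene(s) had no matched protein")
  ct <- stats::cor.test(m$log_fc_gene, m$log_fc_protein)
  structure(list(r = unname(ct$estimate),
                 r_squared = unname(ct$estimate)^2,
                 p = ct$p.value, n_matched = n),
            class = "integration_result")
}
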