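#' Gene-by-sample count matrix with group labels
#'
#' Container for exonic or intronic read counts. Counts must be non-negative
#' integers; gene identifiers must be unique; every sample carries a group
#' label (e.g. \code{"control"} / \code{"knockout"}).
#'
#' @param counts integer matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names sample identifiers.
#' @param groups named character vector mapping each sample (column) name to
#'   its group label, or an unnamed vector in column order.
#' @param feature_class either \code{"exon"} or \code{"intron"}.
#' @return an object of class \code{count_matrix}: a list with elements
#'   \code{counts}, \code{gene_ids}, \code{samples} (data frame with columns
#'   \code{sample}, \code{group}) and \code{feature_class}.
#' @export
count_matrix <- function(counts, groups, feature_class = c("exon", "intron")) {
  feature_class <- match.arg(feature_class)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("counts must have gene identifiers as row names")
  }
  if (is.null(colnames(counts))) {
    stop("counts must have sample identifiers as column names")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated gene identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "counts must be non-negative integers; offending cell: gene '%s', sample '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"
  if (is.null(names(groups))) {
    if (length(groups) != ncol(counts)) {
      stop("groups must have one entry per sample")
    }
    names(groups) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing) > 0) {
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  }
  samples <- data.frame(sample = colnames(counts),
                        group = unname(as.character(groups[colnames(counts)])),
                        stringsAsFactors = FALSE)
  structure(list(counts = counts,
                 gene_ids = rownames(counts),
                 samples = samples,
                 feature_class = feature_class),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d genes x %d samples (%s)\n",
              x$feature_class, nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$samples$group)),
                            as.integer(table(x$samples$group))),
                    collapse = ", ")))
  invisible(x)
}

#' Fluorescence trace set for one imaged islet
#'
#' @param time_s strictly increasing vector of acquisition times (seconds).
#' @param F numeric matrix, one row per cell, one column per timepoint.
#' @param epochs data frame with columns \code{name}, \code{start_s},
#'   \code{end_s} giving the stimulus windows (e.g. 3G, 17G, KCl).
#' @param coords optional data frame of per-cell \code{x}, \code{y} positions.
#' @return an object of class \code{trace_set}.
#' @export
trace_set <- function(time_s, F, epochs, coords = NULL) {
  F <- as.matrix(F)
  if (length(time_s) != ncol(F)) {
    stop("time_s length must equal the number of trace columns")
  }
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  if (any(!is.finite(F))) stop("fluorescence values must be finite")
  if (is.null(rownames(F))) {
    rownames(F) <- sprintf("cell_%02d", seq_len(nrow(F)))
  }
  need <- c("name", "start_s", "end_s")
  if (!all(need %in% names(epochs))) {
    stop("epochs must have columns name, start_s, end_s")
  }
  if (nrow(epochs) == 0) stop("at least one epoch is required")
  if (any(epochs$start_s >= epochs$end_s)) {
    stop("epoch start must precede epoch end")
  }
  o <- order(epochs$start_s)
  epochs <- epochs[o, , drop = FALSE]
  if (nrow(epochs) > 1 &&
      any(epochs$start_s[-1] < epochs$end_s[-nrow(epochs)])) {
    stop("epochs must not overlap")
  }
  if (min(epochs$start_s) < min(time_s) - 1e-9 ||
      max(epochs$end_s) > max(time_s) + 1e-9) {
    stop("epochs must lie within the recorded time range")
  }
  structure(list(time_s = as.numeric(time_s), F = F, epochs = epochs,
                 coords = coords),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d cells x %d timepoints (%.0f-%.0f s); epochs: %s\n",
              nrow(x$F), ncol(x$F), min(x$time_s), max(x$time_s),
              paste(x$epochs$name, collapse = ", ")))
  invisible(x)
}

# index of timepoints falling inside a named epoch; epochs are half-open
# [start, end) so adjacent windows never share a sample, except the final
# epoch which keeps its endpoint
epoch_window <- function(ts, epoch) {
  i <- match(epoch, ts$epochs$name)
  if (is.na(i)) stop(sprintf("epoch '%s' not present", epoch))
  last <- ts$epochs$end_s[i] >= max(ts$epochs$end_s)
  upper <- if (last) ts$time_s <= ts$epochs$end_s[i] else
    ts$time_s < ts$epochs$end_s[i]
  which(ts$time_s >= ts$epochs$start_s[i] & upper)
}

#' Gene set
#'
#' @param name set label.
#' @param genes character vector of gene identifiers; duplicates are removed.
#' @param description optional free-text description.
#' @return an object of class \code{gene_set}.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("a gene set must contain at least one gene")
  genes <- unique(genes)
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' Analysis configuration with validated thresholds
#'
#' @param cpm_min minimum counts-per-million for the expression filter.
#' @param min_samples number of samples that must pass \code{cpm_min}.
#' @param fdr_alpha BH-adjusted significance level, in (0, 1).
#' @param logfc_min optional absolute log2-fold-change threshold.
#' @param polya_threshold_nt poly(A) tail-length threshold (nucleotides).
#' @param n_permutations permutations for empirical nulls (>= 100).
#' @param seed integer seed recorded alongside results.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(cpm_min = 1, min_samples = 3, fdr_alpha = 0.05,
                       logfc_min = 0, polya_threshold_nt = 50,
                       n_permutations = 1000, seed = 1L) {
  if (!(fdr_alpha > 0 && fdr_alpha < 1)) stop("fdr_alpha must be in (0, 1)")
  if (n_permutations < 100) stop("n_permutations must be at least 100")
  if (cpm_min < 0) stop("cpm_min must be non-negative")
  if (min_samples < 1) stop("min_samples must be at least 1")
  structure(list(cpm_min = cpm_min, min_samples = min_samples,
                 fdr_alpha = fdr_alpha, logfc_min = logfc_min,
                 polya_threshold_nt = polya_threshold_nt,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "run_config")
}
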