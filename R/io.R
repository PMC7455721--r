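#' Write a count matrix as TSV
#'
#' Gene rows, sample columns, header row, first column \code{gene_id}.
#' UTF-8, no quoting, no missing values.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param path output TSV path.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' @param path TSV with header, first column \code{gene_id}, one column per
#'   sample, integer counts.
#' @param feature_class \code{"exon"} or \code{"intron"}.
#' @param groups named character vector mapping every sample column to its
#'   group label; unmapped samples are a configuration error.
#' @return a validated \code{\link{count_matrix}}.
#' @export
read_counts <- function(path, feature_class, groups) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (names(df)[1] != "gene_id") stop("first column must be 'gene_id'")
  samples <- names(df)[-1]
  unmapped <- setdiff(samples, names(groups))
  if (length(unmapped) > 0) {
    stop("samples missing from the group map: ",
         paste(unmapped, collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = list(df$gene_id, samples)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-integer or negative count at gene '%s', sample '%s' (value '%s')",
      df$gene_id[bad[1, 1]], samples[bad[1, 2]], m[bad[1, 1], bad[1, 2]]))
  }
  count_matrix(num, groups[samples], feature_class)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then one or more gene ids,
#' tab-separated. Duplicate genes within a set are de-duplicated with a
#' warning.
#'
#' @param path GMT file path.
#' @return list of \code{\link{gene_set}} objects (empty, with a warning, for
#'   an empty file).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(list())
  }
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate gene(s) in set '%s' (line %d) de-duplicated",
                      f[1], i))
    }
    out[[i]] <- gene_set(f[1], genes, f[2])
  }
  out
}

#' Write gene sets in GMT format
#'
#' @param sets list of \code{\link{gene_set}} objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a trace set as CSV plus an epochs sidecar
#'
#' The main CSV has a time column \code{t_s} and one column per cell; the
#' sidecar lists \code{name}, \code{start_s}, \code{end_s} per epoch.
#'
#' @param ts a \code{\link{trace_set}}.
#' @param path traces CSV path.
#' @param epochs_path epochs sidecar CSV path.
#' @export
write_traces <- function(ts, path, epochs_path) {
  stopifnot(inherits(ts, "trace_set"))
  df <- data.frame(t_s = ts$time_s, t(ts$F), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(ts$epochs[, c("name", "start_s", "end_s")], epochs_path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace set from CSV plus an epochs sidecar
#'
#' @param path traces CSV (column \code{t_s} plus one column per cell).
#' @param epochs_path epochs CSV (\code{name}, \code{start_s}, \code{end_s}).
#' @return a \code{\link{trace_set}}.
#' @export
read_traces <- function(path, epochs_path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "t_s") stop("first column must be 't_s'")
  ep <- utils::read.csv(epochs_path, stringsAsFactors = FALSE)
  F <- t(as.matrix(df[, -1, drop = FALSE]))
  trace_set(df$t_s, F, ep)
}

#' Write and read decay courses (CSV)
#'
#' Columns: \code{gene}, \code{genotype}, \code{replicate}, \code{time_hr},
#' \code{relative_abundance} (or \code{value} for raw, un-normalized input).
#'
#' @param course a \code{decay_course} data frame.
#' @param path CSV path.
#' @export
write_decay <- function(course, path) {
  utils::write.csv(course, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("relative_abundance" %in% names(d)) {
    class(d) <- c("decay_course", "data.frame")
  }
  d
}

#' Read a qPCR Ct table (CSV)
#'
#' Columns: \code{sample}, \code{group}, \code{target_ct},
#' \code{reference_ct}.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_ct_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "target_ct", "reference_ct")
  if (!all(need %in% names(d))) {
    stop("Ct table must have columns ", paste(need, collapse = ", "))
  }
  d
}

#' Write a densitogram profile (CSV) and its marker
#'
#' @param profile a \code{densitogram}.
#' @param path profile CSV path (columns \code{position}, \code{intensity}).
#' @param marker_path marker CSV path (columns \code{length_nt},
#'   \code{position}).
#' @export
write_densitogram <- function(profile, path, marker_path) {
  utils::write.csv(data.frame(position = profile$position,
                              intensity = profile$intensity),
                   path, row.names = FALSE, quote = FALSE)
  utils::write.csv(profile$marker, marker_path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_densitogram
#' @param profile_path profile CSV path written by \code{write_densitogram}.
#' @export
read_densitogram <- function(profile_path, marker_path) {
  p <- utils::read.csv(profile_path)
  m <- utils::read.csv(marker_path)
  structure(list(position = p$position, intensity = p$intensity, marker = m),
            class = "densitogram")
}
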