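#' Read an omics table from a delimited text file
#'
#' Expects a rectangular table with a header row and the sample (or feature)
#' identifiers in the first column. Every data cell must be numeric; a
#' non-numeric or missing cell is an error naming its location.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @param samples_in_rows `TRUE` (default) if rows are samples and columns
#'   are features; `FALSE` for the transposed layout (the matrix is
#'   transposed back so samples are always rows on return).
#' @return numeric matrix, samples in rows, with sample and feature names.
#' @export
read_omics_table <- function(path, sep = "\t", samples_in_rows = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("expected an ID column plus at least one data column")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate identifiers in the first column")
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, colnames(df)[-1L]))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric or missing value at row '", rownames(vals)[bad[1L, 1L]],
         "', column '", colnames(vals)[bad[1L, 2L]], "'")
  }
  if (anyDuplicated(colnames(vals))) stop("duplicate feature names in header")
  if (!samples_in_rows) vals <- t(vals)
  vals
}

#' Align two omics tables on their shared samples
#'
#' Inner-joins the two matrices on row (sample) names, preserving the order
#' of the first table. Samples present in only one layer are dropped with a
#' message.
#'
#' @param table1,table2 numeric matrices with sample IDs as row names.
#' @return a [paired_omics] object over the shared samples.
#' @export
align_samples <- function(table1, table2) {
  if (is.null(rownames(table1)) || is.null(rownames(table2)))
    stop("both tables need sample IDs as row names")
  common <- intersect(rownames(table1), rownames(table2))
  if (length(common) == 0L) stop("the two tables share no sample IDs")
  if (length(common) < 3L)
    stop("only ", length(common), " shared sample(s); need at least 3")
  dropped <- (nrow(table1) - length(common)) + (nrow(table2) - length(common))
  if (dropped > 0L)
    message("align_samples: dropped ", dropped,
            " sample(s) absent from one layer")
  paired_omics(table1[common, , drop = FALSE],
               table2[common, , drop = FALSE],
               sample_ids = common)
}

#' Nonparanormal (rank-based Gaussianization) transform
#'
#' Replaces each feature by the standard-normal quantiles of its ranks,
#' `qnorm(rank / (n + 1))`, with average ranks for ties. The transform is
#' monotone per feature, invariant to affine rescaling of the input, and
#' maps continuous skewed features to approximately Gaussian ones.
#'
#' @param X numeric matrix, samples in rows.
#' @return transformed matrix of the same dimensions and dimnames.
#' @export
nonparanormal <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("nonparanormal transform needs at least 3 samples")
  const <- which(apply(X, 2L, function(x) length(unique(x))) < 2L)
  if (length(const)) {
    nm <- colnames(X)[const]
    if (is.null(nm)) nm <- as.character(const)
    stop("constant feature(s): ", paste(nm, collapse = ", "))
  }
  out <- apply(X, 2L, function(x)
    stats::qnorm(rank(x, ties.method = "average") / (n + 1)))
  dimnames(out) <- dimnames(X)
  out
}

#' Write an edge table to a tab-separated file
#'
#' Serializes a [score_edges] table (optionally thresholded at
#' `q < fdr_threshold`) with numeric columns in scientific notation at 12
#' significant digits, so that a write/read round trip is lossless for all
#' practical purposes. Rows are ordered by q-value, p-value, then names.
#'
#' @param edges a [score_edges] data.frame.
#' @param path output file path.
#' @param fdr_threshold keep edges with `q_value < fdr_threshold`
#'   (default `Inf`, i.e. all rows, including degenerate q = 1 edges).
#' @return the path, invisibly.
#' @export
write_edge_table <- function(edges, path, fdr_threshold = Inf) {
  keep <- edges$q_value < fdr_threshold
  out <- edges[keep, , drop = FALSE]
  out <- out[order(out$q_value, out$p_value, out$feature_a, out$feature_b), ]
  for (cl in c("partial_correlation", "p_value", "q_value"))
    out[[cl]] <- sprintf("%.11e", out[[cl]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an edge table written by [write_edge_table]
#'
#' @param path file path.
#' @return data.frame with the standard edge-table columns.
#' @export
read_edge_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE,
                    colClasses = c(feature_a = "character",
                                   feature_b = "character"))
}

# write a paired dataset + truth edge list as TSV (used by the CLI)
.write_dataset <- function(data, truth, prefix) {
  wr <- function(M, path) {
    df <- data.frame(sample_id = rownames(M) %||% paste0("S", seq_len(nrow(M))),
                     apply(M, 2L, function(x) sprintf("%.11e", x)),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(data$X1, paste0(prefix, "_layer1.tsv"))
  wr(data$X2, paste0(prefix, "_layer2.tsv"))
  if (!is.null(truth)) {
    adj <- truth$adjacency
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    el <- data.frame(node_a = rownames(adj)[idx[, 1L]],
                     node_b = colnames(adj)[idx[, 2L]],
                     weight = sprintf("%.11e", truth$theta[idx]))
    utils::write.table(el, paste0(prefix, "_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
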