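#' Paired two-layer omics data
#'
#' Bundles two numeric matrices measured on the same samples into a single
#' object. Rows are samples (aligned across layers), columns are molecular
#' features. Feature names must be unique; names colliding across layers are
#' disambiguated with `"L1:"`/`"L2:"` prefixes. Features that are constant
#' within machine precision are rejected: they carry no covariance signal and
#' would produce a zero shrinkage target.
#'
#' @param X1 numeric matrix, `n` samples x `p1` features (layer 1).
#' @param X2 numeric matrix, `n` samples x `p2` features (layer 2), same row
#'   order as `X1`.
#' @param sample_ids optional character vector of sample identifiers; defaults
#'   to the row names of `X1` (or `"S1"..."Sn"`).
#' @return an object of class `"paired_omics"`: a list with elements `X1`,
#'   `X2`, `sample_ids`, `p1`, `p2`, `n`.
#' @examples
#' d <- paired_omics(matrix(rnorm(40), 10), matrix(rnorm(30), 10))
#' d$p1; d$p2; d$n
#' @export
paired_omics <- function(X1, X2, sample_ids = NULL) {
  X1 <- .as_feature_matrix(X1, "X1", "F1_")
  X2 <- .as_feature_matrix(X2, "X2", "F2_")
  if (nrow(X1) != nrow(X2))
    stop("X1 and X2 must have the same number of rows (paired samples); got ",
         nrow(X1), " and ", nrow(X2))
  n <- nrow(X1)
  if (n < 2L) stop("at least 2 samples are required")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X1)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  if (length(sample_ids) != n) stop("sample_ids must have length n = ", n)
  clash <- intersect(colnames(X1), colnames(X2))
  if (length(clash)) {
    i1 <- colnames(X1) %in% clash
    i2 <- colnames(X2) %in% clash
    colnames(X1)[i1] <- paste0("L1:", colnames(X1)[i1])
    colnames(X2)[i2] <- paste0("L2:", colnames(X2)[i2])
  }
  structure(
    list(X1 = X1, X2 = X2, sample_ids = as.character(sample_ids),
         p1 = ncol(X1), p2 = ncol(X2), n = n),
    class = "paired_omics")
}

.as_feature_matrix <- function(X, what, prefix) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop(what, " must be numeric")
  if (anyNA(X)) stop(what, " contains missing values; impute or filter first")
  if (is.null(colnames(X))) colnames(X) <- paste0(prefix, seq_len(ncol(X)))
  if (anyDuplicated(colnames(X)))
    stop("duplicate feature names in ", what, ": ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "))
  sds <- apply(X, 2L, stats::sd)
  bad <- which(sds <= .Machine$double.eps * colMeans(abs(X)) |
                 !is.finite(sds) | sds == 0)
  if (length(bad))
    stop("constant feature(s) in ", what, ": ",
         paste(colnames(X)[bad], collapse = ", "))
  X
}

#' @export
print.paired_omics <- function(x, ...) {
  cat("paired_omics: ", x$n, " samples, layers of ", x$p1, " + ", x$p2,
      " features\n", sep = "")
  invisible(x)
}

#' Standardize columns to zero mean and unit variance
#'
#' Centers each feature and scales it to unit sample standard deviation
#' (denominator `n - 1`). Constant features are an error.
#'
#' @param X numeric matrix, samples in rows.
#' @return matrix of the same dimensions and dimnames.
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("standardization needs at least 2 samples")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  s <- sqrt(colSums(Xc^2) / (nrow(X) - 1L))
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad)) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("cannot standardize constant feature(s): ", paste(nm, collapse = ", "))
  }
  sweep(Xc, 2L, s, "/")
}

# standardize both layers of a paired_omics object in place
.standardize_pair <- function(data) {
  data$X1 <- standardize(data$X1)
  data$X2 <- standardize(data$X2)
  data
}
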