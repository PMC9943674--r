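#' Empirical block covariances of paired two-layer data
#'
#' Computes the unbiased (denominator `n - 1`) within- and cross-layer sample
#' covariance blocks S11, S12, S22 of a [paired_omics] object, together with
#' the diagonal shrinkage targets (the diagonals of S11 and S22). S21 is never
#' stored; symmetry is structural.
#'
#' @param data a [paired_omics] object.
#' @return an object of class `"block_covariance"`: list with `S11`, `S12`,
#'   `S22`, `mu1`, `mu2`, `t1`, `t2` (target diagonals) and `n`.
#' @export
block_covariances <- function(data) {
  stopifnot(inherits(data, "paired_omics"))
  n <- data$n
  if (n < 2L) stop("covariance estimation needs at least 2 samples")
  mu1 <- colMeans(data$X1)
  mu2 <- colMeans(data$X2)
  C1 <- sweep(data$X1, 2L, mu1, "-")
  C2 <- sweep(data$X2, 2L, mu2, "-")
  S11 <- crossprod(C1) / (n - 1)
  S22 <- crossprod(C2) / (n - 1)
  S12 <- crossprod(C1, C2) / (n - 1)
  structure(
    list(S11 = S11, S12 = S12, S22 = S22, mu1 = mu1, mu2 = mu2,
         t1 = diag(S11), t2 = diag(S22), n = n),
    class = "block_covariance")
}

#' Two-penalty shrunken covariance matrix
#'
#' Assembles the generalized shrinkage estimator: the within-layer blocks are
#' shrunken towards their diagonals with layer-specific intensities,
#' `(1 - lambda_k) * Skk + lambda_k * diag(Skk)`, while the cross-layer block
#' is scaled by `sqrt(1 - lambda1) * sqrt(1 - lambda2)`. With
#' `lambda1 == lambda2` this reduces to ordinary single-penalty shrinkage of
#' the appended data; with `lambda2 == 1` layer 2 decouples completely.
#'
#' @param blocks a [block_covariances] result.
#' @param lambda1,lambda2 shrinkage intensities in `[0, 1]`.
#' @return symmetric `(p1 + p2) x (p1 + p2)` matrix.
#' @export
shrunken_covariance <- function(blocks, lambda1, lambda2) {
  stopifnot(inherits(blocks, "block_covariance"))
  .check_lambda(lambda1, "lambda1")
  .check_lambda(lambda2, "lambda2")
  p1 <- length(blocks$t1)
  p2 <- length(blocks$t2)
  A11 <- (1 - lambda1) * blocks$S11
  diag(A11) <- diag(A11) + lambda1 * blocks$t1
  A22 <- (1 - lambda2) * blocks$S22
  diag(A22) <- diag(A22) + lambda2 * blocks$t2
  A12 <- (sqrt(1 - lambda1) * sqrt(1 - lambda2)) * blocks$S12
  sig <- matrix(0, p1 + p2, p1 + p2)
  sig[seq_len(p1), seq_len(p1)] <- A11
  sig[p1 + seq_len(p2), p1 + seq_len(p2)] <- A22
  sig[seq_len(p1), p1 + seq_len(p2)] <- A12
  sig[p1 + seq_len(p2), seq_len(p1)] <- t(A12)
  nm <- c(rownames(blocks$S11), rownames(blocks$S22))
  dimnames(sig) <- list(nm, nm)
  sig
}

.check_lambda <- function(l, name) {
  if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l < 0 || l > 1)
    stop(name, " must be a single value in [0, 1]")
}

#' Precision matrix from a shrunken covariance
#'
#' Inverts a symmetric positive-definite covariance via its Cholesky
#' factorization and symmetrizes the result. No jitter is added: a failing
#' factorization (e.g. zero shrinkage with more features than samples) is an
#' error, because nonzero shrinkage is the intended remedy.
#'
#' @param sigma symmetric positive-definite matrix.
#' @return the symmetric inverse of `sigma`.
#' @export
precision_matrix <- function(sigma) {
  if (!isSymmetric(unname(sigma), tol = 1e-8))
    stop("sigma must be symmetric")
  ch <- tryCatch(chol(sigma), error = function(e) e)
  if (inherits(ch, "error"))
    stop("covariance is not positive definite; increase the shrinkage ",
         "intensities (lambda1, lambda2 > 0 guarantees invertibility for ",
         "positive targets)")
  th <- chol2inv(ch)
  th <- (th + t(th)) / 2
  dimnames(th) <- dimnames(sigma)
  th
}
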