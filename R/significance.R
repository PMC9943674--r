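#' Partial correlations from a precision matrix
#'
#' `rho_ij = -theta_ij / sqrt(theta_ii * theta_jj)` for `i != j`; the diagonal
#' is stored as zero (self-edges are excluded). Zero entries of the precision
#' matrix map to zero partial correlations, so conditional independencies are
#' preserved exactly.
#'
#' @param theta symmetric precision matrix with strictly positive diagonal.
#' @return matrix of partial correlations with zero diagonal.
#' @export
partial_correlations <- function(theta) {
  d <- diag(theta)
  if (any(d <= 0)) stop("precision matrix has nonpositive diagonal entries")
  sc <- 1 / sqrt(d)
  P <- -theta * tcrossprod(sc)
  diag(P) <- 0
  dimnames(P) <- dimnames(theta)
  P
}

#' Effective shrinkage intensity of a partial-correlation block
#'
#' The shrunken-null density is parameterized by the shrinkage applied to the
#' block an edge lives in: `lambda1` for within-layer-1 edges, `lambda2` for
#' within-layer-2 edges, and `1 - sqrt((1 - lambda1) * (1 - lambda2))` for
#' cross-layer edges -- the complement of the factor that scales the
#' cross-layer covariance block.
#'
#' @param block one of `"11"`, `"12"`, `"22"`.
#' @param lambda1,lambda2 penalties in `[0, 1]`.
#' @return effective shrinkage in `[0, 1]`.
#' @export
effective_lambda <- function(block, lambda1, lambda2) {
  .check_lambda(lambda1, "lambda1")
  .check_lambda(lambda2, "lambda2")
  switch(as.character(block),
         "11" = lambda1,
         "22" = lambda2,
         "12" = 1 - sqrt((1 - lambda1) * (1 - lambda2)),
         stop("unknown block label: ", block))
}

#' Null density of shrunken partial correlations
#'
#' Density of a partial correlation under the null (no conditional
#' association) when the estimate comes from a covariance shrunken with
#' intensity `lambda`:
#' `f(rho) = ((1-lambda)^2 - rho^2)^((kappa-3)/2) /
#'   (Beta(1/2, (kappa-1)/2) * (1-lambda)^(kappa-2))`,
#' supported on `(-(1-lambda), 1-lambda)`. `kappa` plays the role of residual
#' degrees of freedom: without shrinkage and `n >> p` it equals
#' `n - 1 - (p - 2)`.
#'
#' @param rho numeric vector of partial correlations.
#' @param lambda shrinkage intensity in `[0, 1)`.
#' @param kappa shape parameter, `> 1`.
#' @return density values (zero outside the support).
#' @export
null_density <- function(rho, lambda, kappa) {
  if (kappa <= 1) stop("kappa must be > 1")
  if (lambda >= 1) stop("lambda must be < 1 (support degenerates at 1)")
  if (lambda < 0) stop("lambda must be >= 0")
  s <- 1 - lambda
  out <- numeric(length(rho))
  ok <- abs(rho) < s
  out[ok] <- exp(((kappa - 3) / 2) * log(s^2 - rho[ok]^2) -
                   lbeta(0.5, (kappa - 1) / 2) - (kappa - 2) * log(s))
  out
}

#' Two-sided p-value under the shrunken null
#'
#' For `t = |rho| / (1 - lambda)`, the squared scaled statistic `t^2` follows
#' a `Beta(1/2, (kappa-1)/2)` distribution under the null, so the two-sided
#' tail is the regularized incomplete beta tail of `t^2`. Values at or beyond
#' the support edge are clamped just inside it; p-values are floored at the
#' smallest positive normalized double, never exactly zero.
#'
#' @inheritParams null_density
#' @return p-values in `(0, 1]`, same length as `rho`.
#' @export
shrunken_pvalue <- function(rho, lambda, kappa) {
  if (kappa <= 1) stop("kappa must be > 1")
  if (lambda >= 1) stop("lambda must be < 1")
  t <- pmin(abs(rho) / (1 - lambda), 1 - 1e-15)
  p <- stats::pbeta(t^2, 0.5, (kappa - 1) / 2, lower.tail = FALSE)
  pmax(p, .Machine$double.xmin)
}

#' Simulate null partial correlations for a given design
#'
#' Draws a dataset of the same shape as the analyzed one with all entries
#' independent standard normal (so every true partial correlation is zero),
#' runs the full shrinkage estimator with the *supplied* penalties (no
#' re-selection), and returns the resulting partial correlations split by
#' block. These samples calibrate the null density for the observed design.
#'
#' @param n,p1,p2 design of the analyzed data.
#' @param lambda1,lambda2 penalties fixed from the original fit.
#' @param seed RNG seed.
#' @param reps number of independent null datasets to pool (default 1).
#' @param standardize logical; apply the same standardization as the fit.
#' @return list with numeric vectors `b11` (upper triangle of the layer-1
#'   block), `b12` (full cross block), `b22`.
#' @export
simulate_null <- function(n, p1, p2, lambda1, lambda2, seed = 1L,
                          reps = 1L, standardize = TRUE) {
  set.seed(seed)
  out <- list(b11 = NULL, b12 = NULL, b22 = NULL)
  for (r in seq_len(reps)) {
    X1 <- matrix(stats::rnorm(n * p1), n, p1)
    X2 <- matrix(stats::rnorm(n * p2), n, p2)
    d <- paired_omics(X1, X2)
    if (standardize) d <- .standardize_pair(d)
    P <- partial_correlations(precision_matrix(
      shrunken_covariance(block_covariances(d), lambda1, lambda2)))
    i1 <- seq_len(p1); i2 <- p1 + seq_len(p2)
    out$b11 <- c(out$b11, P[i1, i1][upper.tri(P[i1, i1])])
    out$b12 <- c(out$b12, as.vector(P[i1, i2]))
    out$b22 <- c(out$b22, P[i2, i2][upper.tri(P[i2, i2])])
  }
  out
}

#' Fit the null-density shape parameter by maximum likelihood
#'
#' Maximizes the log likelihood of [null_density] over `kappa` on a log scale
#' (bounded 1-D optimization). Samples on or outside the support are clamped
#' just inside before evaluation; if every sample sits at the clamp the fit
#' is meaningless and an error is raised.
#'
#' @param null_samples numeric vector of null partial correlations (>= 100
#'   recommended).
#' @param lambda_eff effective shrinkage of the block, in `[0, 1)`.
#' @return fitted `kappa` (scalar, > 2).
#' @export
fit_kappa <- function(null_samples, lambda_eff) {
  if (lambda_eff >= 1) stop("lambda_eff must be < 1")
  s <- 1 - lambda_eff
  rho <- abs(null_samples)
  clamp <- s * (1 - 1e-12)
  at_clamp <- rho >= clamp
  if (all(at_clamp))
    stop("all null samples lie on the support boundary; cannot fit kappa")
  rho[at_clamp] <- clamp
  N <- length(rho)
  # log f = (kappa-3)/2 * log(s^2 - rho^2) - lbeta(.) - (kappa-2)*log(s)
  L <- sum(log(s^2 - rho^2))
  negll <- function(logk) {
    k <- exp(logk)
    -(((k - 3) / 2) * L - N * lbeta(0.5, (k - 1) / 2) - N * (k - 2) * log(s))
  }
  opt <- stats::optimize(negll, lower = log(2.001), upper = log(1e7),
                         tol = 1e-10)
  exp(opt$minimum)
}

#' Large-sample closed form for the null-density shape
#'
#' `kappa = n - 1 - (p - 2)` with `p = p1 + p2`, valid when `n >> p` and
#' shrinkage is negligible. For `p > n` or `p ~ n` use the empirical MLE path
#' ([simulate_null] + [fit_kappa]) instead.
#'
#' @param n sample count.
#' @param p total number of variables conditioned on (`p1 + p2`).
#' @return `kappa` as a scalar.
#' @export
analytic_kappa <- function(n, p) {
  k <- n - 1 - (p - 2)
  if (k <= 1)
    stop("n - 1 - (p - 2) = ", k, " <= 1: the closed form is degenerate; ",
         "fit kappa empirically (simulate_null + fit_kappa)")
  k
}

#' Calibrate the per-block null distributions
#'
#' Runs the null-simulation + MLE recipe (or the closed form) for the three
#' edge blocks of a fitted model.
#'
#' @param n,p1,p2 design of the analyzed data.
#' @param lambda1,lambda2 penalties from the fit.
#' @param method `"empirical"` (simulate + MLE, the default) or `"analytic"`
#'   (closed form; caller asserts `n >> p`).
#' @param scope `"block"` (default): a separate kappa per edge block, the
#'   layered model's calibration. `"global"`: one kappa fitted on all null
#'   partial correlations pooled -- the layer-agnostic calibration used by
#'   the pooled baseline (requires `lambda1 == lambda2`, so that all blocks
#'   share the same effective shrinkage).
#' @param seed,reps passed to [simulate_null].
#' @param standardize passed to [simulate_null].
#' @return object of class `"null_calibration"`: per block `lambda_eff` and
#'   `kappa`, plus `scope`, `n_null`, `seed`, `method`.
#' @export
calibrate_null <- function(n, p1, p2, lambda1, lambda2,
                           method = c("empirical", "analytic"),
                           scope = c("block", "global"),
                           seed = 1L, reps = 1L, standardize = TRUE) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (scope == "global" && abs(lambda1 - lambda2) > 1e-12)
    stop("global calibration requires a single shared penalty")
  le <- c("11" = effective_lambda("11", lambda1, lambda2),
          "12" = effective_lambda("12", lambda1, lambda2),
          "22" = effective_lambda("22", lambda1, lambda2))
  # at lambda = 1 a block is fully shrunken: its partial correlations are
  # identically zero and carry no evidence. Capping just below 1 keeps the
  # density proper; the p-values of such a block degenerate to 1.
  le <- pmin(le, 1 - 1e-6)
  if (method == "analytic") {
    k <- analytic_kappa(n, p1 + p2)
    kap <- c("11" = k, "12" = k, "22" = k)
    n_null <- 0L
  } else {
    null <- simulate_null(n, p1, p2, lambda1, lambda2, seed = seed,
                          reps = reps, standardize = standardize)
    if (scope == "global") {
      k <- fit_kappa(c(null$b11, null$b12, null$b22), le[["11"]])
      kap <- c("11" = k, "12" = k, "22" = k)
    } else {
      kap <- c("11" = fit_kappa(null$b11, le[["11"]]),
               "12" = fit_kappa(null$b12, le[["12"]]),
               "22" = fit_kappa(null$b22, le[["22"]]))
    }
    n_null <- length(null$b11) + length(null$b12) + length(null$b22)
  }
  structure(list(lambda_eff = le, kappa = kap, n_null = n_null,
                 seed = seed, method = method, scope = scope,
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "null_calibration")
}

#' Score all edges of a fitted partial-correlation network
#'
#' Builds the edge table: one row per unordered variable pair, with its block
#' label, partial correlation, shrunken-null p-value (using the block's
#' effective shrinkage and fitted kappa) and Benjamini-Hochberg q-value.
#' With block-scope calibration (the layered model) the BH adjustment runs
#' *within each block separately*; controlling the FDR at level alpha in each
#' block also controls the overall FDR across blocks at alpha. With global
#' calibration (the layer-agnostic pooled baseline) a single BH adjustment
#' runs across all edges jointly.
#'
#' @param pcor full partial-correlation matrix (layer-1 variables first).
#' @param p1 number of layer-1 variables.
#' @param calibration a [calibrate_null] result.
#' @return `data.frame` with columns `feature_a`, `layer_a`, `feature_b`,
#'   `layer_b`, `block`, `partial_correlation`, `p_value`, `q_value`, sorted
#'   by `q_value` then `p_value`.
#' @export
score_edges <- function(pcor, p1, calibration) {
  stopifnot(inherits(calibration, "null_calibration"))
  p <- ncol(pcor)
  p2 <- p - p1
  nm <- colnames(pcor)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  i1 <- seq_len(p1); i2 <- p1 + seq_len(p2)
  blocks <- list(
    "11" = .block_pairs(pcor[i1, i1, drop = FALSE], nm[i1], nm[i1], 1L, 1L,
                        within = TRUE),
    "12" = .block_pairs(pcor[i1, i2, drop = FALSE], nm[i1], nm[i2], 1L, 2L,
                        within = FALSE),
    "22" = .block_pairs(pcor[i2, i2, drop = FALSE], nm[i2], nm[i2], 2L, 2L,
                        within = TRUE))
  global <- identical(calibration$scope, "global")
  out <- do.call(rbind, lapply(names(blocks), function(b) {
    df <- blocks[[b]]
    df$block <- b
    df$p_value <- shrunken_pvalue(df$partial_correlation,
                                  calibration$lambda_eff[[b]],
                                  calibration$kappa[[b]])
    if (!global)
      df$q_value <- pmax(stats::p.adjust(df$p_value, method = "BH"),
                         .Machine$double.xmin)
    df
  }))
  if (global)
    out$q_value <- pmax(stats::p.adjust(out$p_value, method = "BH"),
                        .Machine$double.xmin)
  out <- out[, c("feature_a", "layer_a", "feature_b", "layer_b", "block",
                 "partial_correlation", "p_value", "q_value")]
  out <- out[order(out$q_value, out$p_value, out$feature_a, out$feature_b), ]
  rownames(out) <- NULL
  out
}

.block_pairs <- function(M, nma, nmb, la, lb, within) {
  if (within) {
    idx <- which(upper.tri(M))
    ia <- ((idx - 1L) %% nrow(M)) + 1L
    ib <- ((idx - 1L) %/% nrow(M)) + 1L
  } else {
    ia <- rep(seq_len(nrow(M)), times = ncol(M))
    ib <- rep(seq_len(ncol(M)), each = nrow(M))
    idx <- cbind(ia, ib)
  }
  data.frame(feature_a = nma[ia], layer_a = la,
             feature_b = nmb[ib], layer_b = lb,
             partial_correlation = M[idx],
             stringsAsFactors = FALSE)
}
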