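#' Moments of the empirical covariance entries
#'
#' Estimates, for every feature pair in each block, the sampling variance of
#' the unbiased covariance entry and its raw second moment. With
#' `w_mij = (x_mi - xbar_i)(x_mj - xbar_j)` and `wbar_ij` the mean over
#' samples,
#' `s_ij = n/(n-1) * wbar_ij`,
#' `var_hat(s_ij) = n/(n-1)^3 * sum_m (w_mij - wbar_ij)^2`, and
#' `E_hat(s_ij^2) = s_ij^2`.
#' These are the classical plug-in moment estimators used to pick shrinkage
#' intensities analytically. Note that `s_ij^2` itself is the unbiased
#' plug-in for the raw second moment (`E[s^2] = var(s) + sigma^2`); adding
#' `var_hat` on top would double-count the sampling variance and visibly
#' biases the selected penalty of a wide sparse layer towards zero (checked
#' against the Monte-Carlo risk surface, see [monte_carlo_risk]). The same
#' convention gives the familiar single-penalty optimum
#' `lambda* = sum var_hat(s_ij) / sum s_ij^2` on the diagonal. Within-layer
#' moments are used for off-diagonal pairs only; cross-layer moments cover
#' the full `p1 x p2` grid.
#'
#' @param data a [paired_omics] object (typically standardized).
#' @return object of class `"covariance_moments"`: per block (`w1`, `w2`,
#'   `cross`) matrices `s`, `var`, `esq`, plus `n`.
#' @export
covariance_moments <- function(data) {
  stopifnot(inherits(data, "paired_omics"))
  n <- data$n
  if (n < 3L) stop("moment estimation needs at least 3 samples")
  C1 <- sweep(data$X1, 2L, colMeans(data$X1), "-")
  C2 <- sweep(data$X2, 2L, colMeans(data$X2), "-")
  structure(
    list(w1 = .pair_moments(C1, C1, n), w2 = .pair_moments(C2, C2, n),
         cross = .pair_moments(C1, C2, n), n = n),
    class = "covariance_moments")
}

# moments for one covariance block from centered data; vectorized:
# sum_m w_mij^2 = crossprod(Ca^2, Cb^2), wbar = crossprod(Ca, Cb)/n
.pair_moments <- function(Ca, Cb, n) {
  wbar <- crossprod(Ca, Cb) / n
  sw2 <- crossprod(Ca^2, Cb^2)
  s <- n / (n - 1) * wbar
  v <- n / (n - 1)^3 * (sw2 - n * wbar^2)
  v[v < 0] <- 0 # guard against negative round-off
  list(s = s, var = v, esq = s^2)
}

#' Coefficients of the shrinkage-risk polynomial
#'
#' Reduces the pairwise covariance moments to the six scalar coefficients of
#' the expected squared Frobenius risk of the two-penalty shrunken covariance,
#' `R(l1, l2) = const + l1*T1_1 + l2*T1_2 + l1^2*T2_1 + l2^2*T2_2 +
#' l1*l2*T3 + sqrt(1-l1)*sqrt(1-l2)*T4`.
#' The additive constant does not depend on the penalties and is never
#' computed; all reported risk values are relative to it.
#'
#' @param moments a [covariance_moments] result.
#' @return object of class `"risk_terms"`: list with `T1_1`, `T1_2`, `T2_1`,
#'   `T2_2`, `T3`, `T4`.
#' @export
risk_terms <- function(moments) {
  stopifnot(inherits(moments, "covariance_moments"))
  off <- function(M) sum(M) - sum(diag(M))
  cross_esq <- sum(moments$cross$esq)
  cross_var <- sum(moments$cross$var)
  out <- list(
    T1_1 = -2 * (off(moments$w1$var) + cross_esq),
    T1_2 = -2 * (off(moments$w2$var) + cross_esq),
    T2_1 = off(moments$w1$esq),
    T2_2 = off(moments$w2$esq),
    T3 = 2 * cross_esq,
    T4 = 4 * (cross_var - cross_esq))
  if (!all(vapply(out, is.finite, logical(1L))))
    stop("non-finite risk terms")
  structure(out, class = "risk_terms")
}

#' Shrinkage risk (up to an additive constant)
#'
#' Evaluates the risk polynomial at given penalties. Vectorized over
#' `lambda1`/`lambda2` of equal length.
#'
#' @param lambda1,lambda2 penalties in `[0, 1]` (vectors allowed).
#' @param terms a [risk_terms] result.
#' @return numeric vector of relative risk values.
#' @export
shrinkage_risk <- function(lambda1, lambda2, terms) {
  stopifnot(inherits(terms, "risk_terms"))
  if (any(!is.finite(lambda1)) || any(lambda1 < 0) || any(lambda1 > 1) ||
      any(!is.finite(lambda2)) || any(lambda2 < 0) || any(lambda2 > 1))
    stop("penalties must lie in [0, 1]")
  lambda1 * terms$T1_1 + lambda2 * terms$T1_2 +
    lambda1^2 * terms$T2_1 + lambda2^2 * terms$T2_2 +
    lambda1 * lambda2 * terms$T3 +
    sqrt(1 - lambda1) * sqrt(1 - lambda2) * terms$T4
}

#' Select the two shrinkage penalties by risk minimization
#'
#' Minimizes [shrinkage_risk] over the closed unit square with a coarse grid
#' (default 101 x 101) followed by derivative-free local grid refinement
#' around the best point. A grid-based scheme is used deliberately: the
#' `sqrt(1 - lambda)` term has unbounded slope at the boundary `lambda = 1`,
#' which is part of the search space. Exact risk ties are broken towards the
#' smaller `lambda1 + lambda2`.
#'
#' @param terms a [risk_terms] result.
#' @param grid_n number of coarse grid points per axis.
#' @return object of class `"lambda_estimate"`: list with `lambda1`,
#'   `lambda2`, `risk_value` (relative), `constrained = FALSE`.
#' @export
select_lambdas <- function(terms, grid_n = 101L) {
  stopifnot(inherits(terms, "risk_terms"))
  g <- seq(0, 1, length.out = grid_n)
  L1 <- rep(g, times = grid_n)
  L2 <- rep(g, each = grid_n)
  r <- shrinkage_risk(L1, L2, terms)
  best <- .risk_tie_break(r, L1 + L2)
  l1 <- L1[best]; l2 <- L2[best]
  h <- (g[2L] - g[1L])
  for (round in 1:3) {
    g1 <- .local_grid(l1, h)
    g2 <- .local_grid(l2, h)
    L1 <- rep(g1, times = length(g2))
    L2 <- rep(g2, each = length(g1))
    r <- shrinkage_risk(L1, L2, terms)
    best <- .risk_tie_break(r, L1 + L2)
    l1 <- L1[best]; l2 <- L2[best]
    h <- h / 20
  }
  structure(list(lambda1 = l1, lambda2 = l2,
                 risk_value = shrinkage_risk(l1, l2, terms),
                 constrained = FALSE),
            class = "lambda_estimate")
}

.local_grid <- function(center, h, k = 41L) {
  unique(pmin(1, pmax(0, seq(center - h, center + h, length.out = k))))
}

.risk_tie_break <- function(r, size) {
  cand <- which(r <= min(r))
  cand[which.min(size[cand])]
}

#' Select a single shared penalty (pooled-layer baseline)
#'
#' Minimizes the risk along the diagonal `lambda1 = lambda2`, i.e. ordinary
#' single-penalty covariance shrinkage of the appended two-layer data. This is
#' the layer-agnostic baseline estimator against which the two-penalty model
#' is benchmarked.
#'
#' @inheritParams select_lambdas
#' @return a `"lambda_estimate"` with `lambda1 == lambda2` and
#'   `constrained = TRUE`.
#' @export
select_lambda_diagonal <- function(terms, grid_n = 1001L) {
  stopifnot(inherits(terms, "risk_terms"))
  g <- seq(0, 1, length.out = grid_n)
  r <- shrinkage_risk(g, g, terms)
  l <- g[.risk_tie_break(r, 2 * g)]
  h <- g[2L] - g[1L]
  for (round in 1:3) {
    gg <- .local_grid(l, h)
    r <- shrinkage_risk(gg, gg, terms)
    l <- gg[.risk_tie_break(r, 2 * gg)]
    h <- h / 20
  }
  structure(list(lambda1 = l, lambda2 = l,
                 risk_value = shrinkage_risk(l, l, terms),
                 constrained = TRUE),
            class = "lambda_estimate")
}

#' Monte-Carlo estimate of the true shrinkage risk
#'
#' Averages `||Sigma_hat(l1, l2) - Sigma_true||_F^2` over repeated datasets
#' drawn from `N(0, Sigma_true)`, for every penalty pair on a grid. Used only
#' to validate the analytic risk surface; each replicate's contribution is
#' reduced to a few scalar products so the grid evaluation itself is free.
#' Data are used as drawn (no standardization), matching the definition of
#' the risk in terms of the covariance of the observed variables.
#'
#' @param sigma_true true covariance, symmetric positive definite.
#' @param p1 number of layer-1 variables (first `p1` rows/columns).
#' @param lambda1_grid,lambda2_grid penalty grids.
#' @param n samples per replicate.
#' @param reps number of replicates.
#' @param seed RNG seed.
#' @return matrix of mean risks, rows indexed by `lambda1_grid`, columns by
#'   `lambda2_grid`.
#' @export
monte_carlo_risk <- function(sigma_true, p1, lambda1_grid, lambda2_grid,
                             n, reps = 100L, seed = 1L) {
  if (reps < 1L) stop("reps must be >= 1")
  ch <- tryCatch(chol(sigma_true), error = function(e)
    stop("sigma_true must be positive definite"))
  p <- ncol(sigma_true)
  i1 <- seq_len(p1); i2 <- (p1 + 1L):p
  Sig11 <- sigma_true[i1, i1]; Sig22 <- sigma_true[i2, i2]
  Sig12 <- sigma_true[i1, i2]
  acc <- c(a1 = 0, b1 = 0, c1 = 0, a2 = 0, b2 = 0, c2 = 0,
           u = 0, v = 0, w = 0)
  set.seed(seed)
  for (r in seq_len(reps)) {
    X <- matrix(stats::rnorm(n * p), n, p) %*% ch
    Xc <- sweep(X, 2L, colMeans(X), "-")
    S <- crossprod(Xc) / (n - 1)
    S11 <- S[i1, i1]; S22 <- S[i2, i2]; S12 <- S[i1, i2]
    # within block k: ||D + lambda*E||^2, D = S - Sig, E = diag(S) - S
    D1 <- S11 - Sig11; E1 <- diag(diag(S11)) - S11
    D2 <- S22 - Sig22; E2 <- diag(diag(S22)) - S22
    acc <- acc + c(sum(D1^2), sum(D1 * E1), sum(E1^2),
                   sum(D2^2), sum(D2 * E2), sum(E2^2),
                   sum(Sig12^2), sum(S12 * Sig12), sum(S12^2))
  }
  acc <- acc / reps
  cf <- sqrt(outer(1 - lambda1_grid, 1 - lambda2_grid))
  R <- outer(acc["a1"] + 2 * lambda1_grid * acc["b1"] +
               lambda1_grid^2 * acc["c1"],
             acc["a2"] + 2 * lambda2_grid * acc["b2"] +
               lambda2_grid^2 * acc["c2"], "+") +
    2 * (acc["u"] - 2 * cf * acc["v"] + cf^2 * acc["w"])
  dimnames(R) <- list(signif(lambda1_grid, 10), signif(lambda2_grid, 10))
  R
}
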