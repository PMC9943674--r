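# independent brute-force oracles used across the test files

# O(n p^2) double-loop unbiased covariance
loop_covariance <- function(A, B) {
  n <- nrow(A)
  out <- matrix(0, ncol(A), ncol(B))
  mua <- colMeans(A); mub <- colMeans(B)
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
    acc <- 0
    for (m in seq_len(n))
      acc <- acc + (A[m, i] - mua[i]) * (B[m, j] - mub[j])
    out[i, j] <- acc / (n - 1)
  }
  out
}

# explicit triple-loop moment estimators for one block
loop_moments <- function(A, B) {
  n <- nrow(A)
  mua <- colMeans(A); mub <- colMeans(B)
  s <- v <- e <- matrix(0, ncol(A), ncol(B))
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
    w <- numeric(n)
    for (m in seq_len(n))
      w[m] <- (A[m, i] - mua[i]) * (B[m, j] - mub[j])
    wbar <- mean(w)
    s[i, j] <- n / (n - 1) * wbar
    v[i, j] <- n / (n - 1)^3 * sum((w - wbar)^2)
    e[i, j] <- s[i, j]^2
  }
  list(s = s, var = v, esq = e)
}

# exhaustive pairwise-comparison U-statistic AUC for the (q, p, |rho|)
# lexicographic ranking (smaller q, then smaller p, then larger |rho| wins)
exhaustive_auc <- function(edge_table, labels) {
  better <- function(i, j) {
    a <- c(edge_table$q_value[i], edge_table$p_value[i],
           -abs(edge_table$partial_correlation[i]))
    b <- c(edge_table$q_value[j], edge_table$p_value[j],
           -abs(edge_table$partial_correlation[j]))
    for (k in 1:3) {
      if (a[k] < b[k]) return(1)
      if (a[k] > b[k]) return(0)
    }
    0.5
  }
  ti <- which(labels); fi <- which(!labels)
  acc <- 0
  for (i in ti) for (j in fi) acc <- acc + better(i, j)
  acc / (length(ti) * length(fi))
}

# two-sided tail p-value by adaptive quadrature of the null density
quadrature_pvalue <- function(rho, lambda, kappa) {
  s <- 1 - lambda
  a <- min(abs(rho), s)
  if (a >= s) return(0)
  2 * stats::integrate(function(x) null_density(x, lambda, kappa),
                       a, s, rel.tol = 1e-12)$value
}

# draws from the shrunken null density: t^2 ~ Beta(1/2, (kappa-1)/2),
# rho = sign * (1-lambda) * t
rnull_density <- function(m, lambda, kappa) {
  t <- sqrt(stats::rbeta(m, 0.5, (kappa - 1) / 2))
  sample(c(-1, 1), m, replace = TRUE) * (1 - lambda) * t
}

# a small fake ground-truth object for scoring oracles
fake_truth <- function(adjacency) {
  structure(list(adjacency = adjacency, theta = adjacency * 0.1,
                 p1 = nrow(adjacency), p2 = 0L),
            class = "ground_truth")
}

# random risk terms with the signs the estimators produce in practice
random_terms <- function(seed) {
  set.seed(seed)
  structure(list(T1_1 = -abs(rnorm(1, 5)), T1_2 = -abs(rnorm(1, 5)),
                 T2_1 = abs(rnorm(1, 4)), T2_2 = abs(rnorm(1, 4)),
                 T3 = abs(rnorm(1, 2)), T4 = -abs(rnorm(1, 3))),
            class = "risk_terms")
}
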