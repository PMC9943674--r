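test_that("covariance moments match an explicit triple-loop oracle", {
  set.seed(3)
  d <- paired_omics(matrix(rnorm(24), 8, 3), matrix(rnorm(32), 8, 4))
  m <- covariance_moments(d)
  for (blk in list(list(m$w1, d$X1, d$X1), list(m$w2, d$X2, d$X2),
                   list(m$cross, d$X1, d$X2))) {
    o <- loop_moments(blk[[2]], blk[[3]])
    expect_equal(unname(blk[[1]]$s), o$s, tolerance = 1e-12)
    expect_equal(unname(blk[[1]]$var), o$var, tolerance = 1e-12)
    expect_equal(unname(blk[[1]]$esq), o$esq, tolerance = 1e-12)
  }
  expect_error(covariance_moments(paired_omics(matrix(rnorm(2)),
                                               matrix(rnorm(2)))),
               "at least 3")
})

test_that("moment edge cases: constant features and symmetric pairs", {
  # constant feature: all w_m identical, so var_hat = 0 (internal helper;
  # the public container rejects constant features at load time)
  C <- cbind(c(1, -1, 0, 2, -2), rep(0, 5))
  pm <- shrinknet:::.pair_moments(sweep(C, 2, colMeans(C)),
                                  sweep(C, 2, colMeans(C)), 5)
  expect_equal(pm$var[1, 2], 0)
  expect_equal(pm$esq[1, 2], pm$s[1, 2]^2)

  # y identical to x: cross-pair variance equals the single-feature variance
  x <- c(1, -1, 0, 2, -0.5, 0.3)
  m <- covariance_moments(paired_omics(matrix(x), matrix(x)))
  expect_equal(m$cross$var[1, 1], m$w1$var[1, 1])
})

test_that("risk terms reduce the moment tables correctly", {
  set.seed(5)
  d <- paired_omics(matrix(rnorm(40), 10, 4), matrix(rnorm(30), 10, 3))
  m <- covariance_moments(d)
  tr <- risk_terms(m)
  off <- function(M) sum(M) - sum(diag(M))
  expect_equal(tr$T1_1, -2 * (off(m$w1$var) + sum(m$cross$esq)))
  expect_equal(tr$T1_2, -2 * (off(m$w2$var) + sum(m$cross$esq)))
  expect_equal(tr$T2_1, off(m$w1$esq))
  expect_equal(tr$T2_2, off(m$w2$esq))
  expect_equal(tr$T3, 2 * sum(m$cross$esq))
  expect_equal(tr$T4, 4 * (sum(m$cross$var) - sum(m$cross$esq)))

  # single feature per layer: no within-layer off-diagonal pairs
  m1 <- covariance_moments(paired_omics(matrix(rnorm(6)), matrix(rnorm(6))))
  t1 <- risk_terms(m1)
  expect_equal(t1$T2_1, 0)
  expect_equal(t1$T2_2, 0)
  expect_equal(t1$T3, 2 * m1$cross$esq[1, 1])
})

test_that("risk polynomial evaluates the six-term sum", {
  tr <- structure(list(T1_1 = -2, T1_2 = -3, T2_1 = 1.5, T2_2 = 2.5,
                       T3 = 0.5, T4 = -4), class = "risk_terms")
  expect_equal(shrinkage_risk(0, 0, tr), -4)
  expect_equal(shrinkage_risk(1, 1, tr), -2 - 3 + 1.5 + 2.5 + 0.5)
  expect_equal(shrinkage_risk(0.5, 0.25, tr),
               0.5 * -2 + 0.25 * -3 + 0.25 * 1.5 + 0.0625 * 2.5 +
                 0.125 * 0.5 + sqrt(0.5) * sqrt(0.75) * -4)
  expect_error(shrinkage_risk(1.5, 0, tr), "\\[0, 1\\]")
})

test_that("the 2-D selector matches a dense-grid oracle", {
  g <- seq(0, 1, length.out = 1001)
  for (seed in c(2, 17, 31, 44)) {
    tr <- random_terms(seed)
    sel <- select_lambdas(tr)
    L1 <- rep(g, times = 1001); L2 <- rep(g, each = 1001)
    r <- shrinkage_risk(L1, L2, tr)
    i <- which.min(r)
    expect_lt(abs(sel$lambda1 - L1[i]), 1e-3)
    expect_lt(abs(sel$lambda2 - L2[i]), 1e-3)
    expect_lte(sel$risk_value, min(r) + 1e-12)
  }
})

test_that("selector degenerate regimes follow the closed forms", {
  # T3 = T4 = 0: separable quadratics, argmin = clip(-T1/(2 T2), 0, 1)
  tr <- structure(list(T1_1 = -3, T1_2 = -10, T2_1 = 2, T2_2 = 4,
                       T3 = 0, T4 = 0), class = "risk_terms")
  sel <- select_lambdas(tr)
  expect_equal(sel$lambda1, 0.75, tolerance = 1e-6)
  expect_equal(sel$lambda2, 1, tolerance = 1e-6) # clipped at the boundary

  # nonnegative linear terms and T4 = 0: risk nondecreasing, argmin at 0
  tr0 <- structure(list(T1_1 = 1, T1_2 = 0.5, T2_1 = 2, T2_2 = 1,
                        T3 = 0.2, T4 = 0), class = "risk_terms")
  sel0 <- select_lambdas(tr0)
  expect_equal(c(sel0$lambda1, sel0$lambda2), c(0, 0))
})

test_that("the diagonal selector is consistent with the 2-D problem", {
  g <- seq(0, 1, length.out = 2001)
  for (seed in c(6, 23)) {
    tr <- random_terms(seed)
    sel <- select_lambda_diagonal(tr)
    r <- shrinkage_risk(g, g, tr)
    expect_lt(abs(sel$lambda1 - g[which.min(r)]), 1e-3)
    expect_equal(sel$lambda1, sel$lambda2)
    expect_true(sel$constrained)
    # constrained minimum can never beat the unconstrained one
    expect_gte(sel$risk_value, select_lambdas(tr)$risk_value - 1e-12)
  }
  # symmetric terms: the free optimum sits on the diagonal
  trs <- structure(list(T1_1 = -4, T1_2 = -4, T2_1 = 3, T2_2 = 3,
                        T3 = 1, T4 = -2), class = "risk_terms")
  expect_equal(select_lambdas(trs)$lambda1,
               select_lambda_diagonal(trs)$lambda1, tolerance = 1e-6)
})

test_that("monte_carlo_risk is deterministic and matches direct assembly", {
  set.seed(8)
  A <- matrix(rnorm(36), 6)
  sig <- crossprod(A) / 6 + diag(6)
  g <- c(0, 0.3, 0.7, 1)
  R1 <- monte_carlo_risk(sig, 2, g, g, n = 25, reps = 3, seed = 99)
  R2 <- monte_carlo_risk(sig, 2, g, g, n = 25, reps = 3, seed = 99)
  expect_identical(R1, R2)

  # direct oracle: rebuild Sigma_hat per replicate with the same RNG stream
  ch <- chol(sig)
  set.seed(99)
  acc <- matrix(0, length(g), length(g))
  for (r in 1:3) {
    X <- matrix(rnorm(25 * 6), 25, 6) %*% ch
    b <- block_covariances(paired_omics(X[, 1:2], X[, 3:6]))
    for (i in seq_along(g)) for (j in seq_along(g))
      acc[i, j] <- acc[i, j] +
        sum((shrunken_covariance(b, g[i], g[j]) - sig)^2)
  }
  expect_equal(unname(R1), acc / 3, tolerance = 1e-10)
  expect_error(monte_carlo_risk(matrix(c(1, 2, 2, 1), 2), 1, g, g, 10),
               "positive definite")
})

test_that("selected penalties shrink towards zero as n grows", {
  cfg <- sim_config(10, 20, densities = c(0.1, 0.05, 0.05))
  truth <- generate_precision(cfg, seed = 2)
  lam <- sapply(c(50, 400, 3200), function(n) {
    d <- shrinknet:::.standardize_pair(sample_dataset(truth, n, seed = n))
    sel <- select_lambdas(risk_terms(covariance_moments(d)))
    c(sel$lambda1, sel$lambda2)
  })
  expect_true(all(diff(t(lam)[, 1]) < 0))
  expect_true(all(diff(t(lam)[, 2]) < 0))
  expect_lt(max(lam[, 3]), 0.1)
})
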