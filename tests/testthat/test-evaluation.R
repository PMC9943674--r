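test_that("gaussian log likelihood matches direct evaluation", {
  # hand 2x2 instance
  X <- rbind(c(1, 0), c(-1, 2), c(0.5, 1))
  theta <- rbind(c(2, -0.5), c(-0.5, 1))
  Xc <- sweep(X, 2, colMeans(X))
  Sn <- crossprod(Xc) / 3
  expect_equal(gaussian_log_likelihood(theta, X),
               3 / 2 * (log(det(theta)) - sum(diag(Sn %*% theta))))

  # identity precision on standardized data: exactly -p (n-1) / 2
  set.seed(2)
  Z <- standardize(matrix(rnorm(40 * 6), 40, 6))
  expect_equal(gaussian_log_likelihood(diag(6), Z), -6 * 39 / 2,
               tolerance = 1e-9)

  # the in-sample MLE beats perturbed alternatives
  set.seed(3)
  X <- matrix(rnorm(200 * 4), 200, 4)
  Sn <- crossprod(sweep(X, 2, colMeans(X))) / 200
  best <- gaussian_log_likelihood(solve(Sn), X)
  for (eps in c(0.2, 0.5))
    expect_gt(best, gaussian_log_likelihood(solve(Sn + eps * diag(4)), X))
  expect_error(gaussian_log_likelihood(matrix(c(1, 2, 2, 1), 2),
                                       matrix(rnorm(10), 5)),
               "positive definite")
})

test_that("ROC AUC matches the exhaustive pairwise oracle", {
  set.seed(5)
  for (rep in 1:4) {
    m <- 18
    et <- data.frame(q_value = round(runif(m), 1), # coarse: forces ties
                     p_value = round(runif(m), 1),
                     partial_correlation = round(runif(m, -1, 1), 1))
    lab <- runif(m) < 0.4
    if (!any(lab) || all(lab)) next
    # route through a fake truth whose adjacency encodes the labels
    adj <- matrix(FALSE, m + 1, m + 1,
                  dimnames = list(paste0("v", 0:m), paste0("v", 0:m)))
    et$feature_a <- "v0"
    et$feature_b <- paste0("v", 1:m)
    adj["v0", paste0("v", which(lab))] <- TRUE
    expect_equal(edge_recovery_auc(et, fake_truth(adj)),
                 exhaustive_auc(et, lab))
  }
})

test_that("AUC is invariant under monotone transforms and hits the limits", {
  et <- data.frame(q_value = c(.01, .02, .2, .5, .7, .9),
                   p_value = c(.001, .005, .1, .4, .6, .8),
                   partial_correlation = c(.5, .4, .3, .2, .1, .05),
                   feature_a = "v0", feature_b = paste0("v", 1:6))
  adj <- matrix(FALSE, 7, 7, dimnames = list(paste0("v", 0:6),
                                             paste0("v", 0:6)))
  adj["v0", c("v1", "v2")] <- TRUE
  tr <- fake_truth(adj)
  expect_equal(edge_recovery_auc(et, tr), 1) # perfect separation
  et2 <- et
  et2$q_value <- qnorm(et$q_value / 2 + 0.2) # strictly increasing map
  et2$p_value <- et$p_value^3
  expect_equal(edge_recovery_auc(et2, tr), edge_recovery_auc(et, tr))

  # degenerate truths: undefined AUC
  adj0 <- adj; adj0[] <- FALSE
  expect_true(is.na(edge_recovery_auc(et, fake_truth(adj0))))

  # random ranking concentrates near 1/2
  set.seed(11)
  etr <- data.frame(q_value = runif(4000), p_value = runif(4000),
                    partial_correlation = runif(4000),
                    feature_a = "v0", feature_b = paste0("w", 1:4000))
  adjr <- matrix(FALSE, 4001, 4001,
                 dimnames = list(c("v0", paste0("w", 1:4000)),
                                 c("v0", paste0("w", 1:4000))))
  adjr["v0", sample(paste0("w", 1:4000), 800)] <- TRUE
  expect_equal(edge_recovery_auc(etr, fake_truth(adjr)), 0.5,
               tolerance = 0.05)
})

test_that("average precision matches hand computation and its baseline", {
  # ranking: T F T F F F -> precisions at hits 1/1 and 2/3, AP = 5/6
  et <- data.frame(q_value = seq(0.1, 0.6, by = 0.1), p_value = 1e-3,
                   partial_correlation = 0.1,
                   feature_a = "v0", feature_b = paste0("v", 1:6))
  adj <- matrix(FALSE, 7, 7, dimnames = list(paste0("v", 0:6),
                                             paste0("v", 0:6)))
  adj["v0", c("v1", "v3")] <- TRUE
  expect_equal(edge_recovery_aucpr(et, fake_truth(adj)),
               (1 + 2 / 3) / 2)
  # perfect ranking
  adj2 <- adj; adj2[] <- FALSE; adj2["v0", c("v1", "v2")] <- TRUE
  expect_equal(edge_recovery_aucpr(et, fake_truth(adj2)), 1)
  # random ranking: AP concentrates near prevalence
  set.seed(13)
  etr <- data.frame(q_value = runif(5000), p_value = runif(5000),
                    partial_correlation = runif(5000),
                    feature_a = "v0", feature_b = paste0("w", 1:5000))
  adjr <- matrix(FALSE, 5001, 5001,
                 dimnames = list(c("v0", paste0("w", 1:5000)),
                                 c("v0", paste0("w", 1:5000))))
  adjr["v0", sample(paste0("w", 1:5000), 1000)] <- TRUE
  expect_equal(edge_recovery_aucpr(etr, fake_truth(adjr)), 0.2,
               tolerance = 0.05)
})

test_that("observed FDR counts false discoveries among q < alpha calls", {
  et <- data.frame(q_value = c(.01, .02, .04, .9), p_value = c(.01, .02, .04, .9),
                   partial_correlation = .2,
                   feature_a = "v0", feature_b = paste0("v", 1:4))
  adj <- matrix(FALSE, 5, 5, dimnames = list(paste0("v", 0:4),
                                             paste0("v", 0:4)))
  adj["v0", c("v1", "v3")] <- TRUE # of the 3 discoveries, v2 is false
  expect_equal(observed_fdr(et, fake_truth(adj), alpha = 0.05), 1 / 3)
  adj[] <- FALSE; adj["v0", paste0("v", 1:3)] <- TRUE
  expect_equal(observed_fdr(et, fake_truth(adj), alpha = 0.05), 0)
  expect_true(is.na(observed_fdr(et, fake_truth(adj), alpha = 0.001)))
})

test_that("estimators constrained to the same penalties are identical", {
  cfg <- sim_config(8, 12, densities = c(0.1, 0.05, 0.05))
  truth <- generate_precision(cfg, seed = 3)
  d <- sample_dataset(truth, 60, seed = 4)
  f1 <- shrinknet(d, lambdas = c(0.5, 0.5), null_seed = 6)
  f2 <- shrinknet(d, lambdas = c(0.5, 0.5), null_seed = 6)
  expect_identical(f1$edges, f2$edges)
  expect_equal(edge_recovery_auc(f1$edges, truth) -
                 edge_recovery_auc(f2$edges, truth), 0)
  expect_equal(gaussian_log_likelihood(f1$theta, cbind(d$X1, d$X2)) -
                 gaussian_log_likelihood(f2$theta, cbind(d$X1, d$X2)), 0)
})

test_that("sample-size scans are deterministic with correct minimal-n logic", {
  expect_equal(sample_size_grid(400), c(64L, 90L, 128L, 181L, 256L, 362L))
  expect_equal(sample_size_grid()[c(1, 17)], c(64L, 16384L))
  cfg <- sim_config(8, 16, densities = c(0.15, 0.08, 0.08))
  s1 <- sample_size_scan(cfg, "layered", grid = c(30L, 120L), reps = 2,
                         base_seed = 5)
  s2 <- sample_size_scan(cfg, "layered", grid = c(30L, 120L), reps = 2,
                         base_seed = 5)
  expect_identical(s1$replicates, s2$replicates)
  expect_true(all(c("auc", "auc_pr", "fdr", "lambda1") %in%
                    names(s1$replicates)))
  # minimal_n is the first grid point whose median AUC clears the threshold
  med <- s1$summary$median_auc
  grid <- s1$summary$n
  hit <- which(med > 0.8)
  expect_equal(s1$minimal_n,
               if (length(hit)) grid[min(hit)] else NA_integer_)
  expect_error(sample_size_scan(cfg, "layered", grid = c(100L, 50L)),
               "increasing")
})

test_that("paired difference curves share data within a replicate", {
  cfg <- sim_config(8, 16, densities = c(0.15, 0.08, 0.08))
  cv <- auc_difference_curve(cfg, grid = c(80L), reps = 3, base_seed = 9)
  expect_equal(nrow(cv$replicates), 3)
  expect_equal(cv$replicates$auc_diff,
               cv$replicates$auc_layered - cv$replicates$auc_pooled)
  expect_equal(cv$max_median_diff, median(cv$replicates$auc_diff))
  lk <- likelihood_difference_curve(cfg, grid = c(80L), reps = 2,
                                    test_n = 100L, base_seed = 9)
  expect_equal(lk$replicates$loglik_diff,
               lk$replicates$loglik_layered - lk$replicates$loglik_pooled)
})
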