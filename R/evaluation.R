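#' Gaussian log likelihood of a precision matrix on held-out data
#'
#' `l(Theta) = (n/2) * (log|Theta| - Tr(S_n Theta))` with `S_n` the
#' `1/n`-scaled second-moment matrix of the test sample about its own mean.
#'
#' @param theta symmetric positive-definite precision matrix.
#' @param X_test test data matrix with `ncol(X_test) == ncol(theta)`.
#' @return scalar log likelihood (up to the additive normalization constant
#'   `-np/2 log(2 pi)`).
#' @export
gaussian_log_likelihood <- function(theta, X_test) {
  X_test <- as.matrix(X_test)
  if (ncol(X_test) != ncol(theta)) stop("dimension mismatch")
  n <- nrow(X_test)
  ch <- tryCatch(chol(theta), error = function(e)
    stop("theta must be positive definite"))
  Xc <- sweep(X_test, 2L, colMeans(X_test), "-")
  Sn <- crossprod(Xc) / n
  logdet <- 2 * sum(log(diag(ch)))
  n / 2 * (logdet - sum(Sn * theta))
}

# midranks of edges under the recovery ranking: ascending q-value, ties by
# ascending p-value, then by descending |rho|; remaining exact ties get
# average ranks (Mann-Whitney tie correction)
.edge_midranks <- function(q, p, arho) {
  n <- length(q)
  o <- order(q, p, -arho)
  qs <- q[o]; ps <- p[o]; as <- arho[o]
  new_grp <- c(TRUE, qs[-1L] != qs[-n] | ps[-1L] != ps[-n] |
                 as[-1L] != as[-n])
  g <- cumsum(new_grp)
  cnt <- tabulate(g)
  end <- cumsum(cnt)
  mid <- end - (cnt - 1) / 2
  r <- numeric(n)
  r[o] <- mid[g]
  r
}

# truth labels for an edge table, via the adjacency dimnames
.edge_labels <- function(edge_table, truth) {
  nodes <- rownames(truth$adjacency)
  ia <- match(edge_table$feature_a, nodes)
  ib <- match(edge_table$feature_b, nodes)
  if (anyNA(ia) || anyNA(ib))
    stop("edge table features not found in the ground truth")
  truth$adjacency[cbind(ia, ib)]
}

#' Edge-recovery ROC AUC
#'
#' Area under the ROC curve for ranking all unordered variable pairs by
#' their adjusted significance -- ascending q-value, ties broken by
#' ascending p-value and then by descending absolute partial correlation --
#' against the ground-truth adjacency, computed via the Mann-Whitney U
#' statistic with midrank tie correction. Ranking by the adjusted values is
#' what makes the per-block calibration of the layered model visible to the
#' ROC analysis: with unbalanced designs the block-wise adjustment promotes
#' edges from small or densely connected blocks.
#'
#' @param edge_table a [score_edges] table covering all pairs of `truth`.
#' @param truth a [generate_precision] result.
#' @return AUC in `[0, 1]`, or `NA` if the truth has zero or only edges.
#' @export
edge_recovery_auc <- function(edge_table, truth) {
  lab <- .edge_labels(edge_table, truth)
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- .edge_midranks(edge_table$q_value, edge_table$p_value,
                      abs(edge_table$partial_correlation))
  (n1 * n0 + n1 * (n1 + 1) / 2 - sum(r[lab])) / (n1 * n0)
}

#' Edge-recovery precision-recall AUC (average precision)
#'
#' Step-wise average precision of the same ranking as [edge_recovery_auc]:
#' the mean, over true edges, of the precision at each true edge's rank.
#'
#' @inheritParams edge_recovery_auc
#' @return average precision in `[0, 1]`, or `NA` if degenerate.
#' @export
edge_recovery_aucpr <- function(edge_table, truth) {
  lab <- .edge_labels(edge_table, truth)
  n1 <- sum(lab)
  if (n1 == 0L || n1 == length(lab)) return(NA_real_)
  o <- order(edge_table$q_value, edge_table$p_value,
             -abs(edge_table$partial_correlation))
  ls <- lab[o]
  prec <- cumsum(ls) / seq_along(ls)
  sum(prec[ls]) / n1
}

#' Observed false discovery rate of the thresholded network
#'
#' Fraction of edges called at `q < alpha` that are absent from the ground
#' truth. With no discoveries the FDR is undefined and `NA` is returned
#' (recording 0 would bias calibration summaries).
#'
#' @inheritParams edge_recovery_auc
#' @param alpha q-value threshold (default 0.05).
#' @return observed FDR in `[0, 1]`, or `NA` with no discoveries.
#' @export
observed_fdr <- function(edge_table, truth, alpha = 0.05) {
  lab <- .edge_labels(edge_table, truth)
  disc <- edge_table$q_value < alpha
  if (!any(disc)) return(NA_real_)
  mean(!lab[disc])
}

# one simulation replicate: truth + dataset + fit(s) + recovery metrics.
# seeds are strided so truth/data/null streams never collide across
# replicates.
.run_replicate <- function(config, n, estimators, seed, alpha = 0.05,
                           test_n = 0L, edges = TRUE) {
  truth <- generate_precision(config, seed = seed)
  dat <- sample_dataset(truth, n, seed = seed + 1L)
  res <- lapply(estimators, function(est) {
    fit <- shrinknet(dat, estimator = est, null_seed = seed + 2L,
                     compute_edges = edges)
    out <- list(lambda1 = fit$lambdas[[1L]], lambda2 = fit$lambdas[[2L]])
    if (edges) {
      out$auc <- edge_recovery_auc(fit$edges, truth)
      out$auc_pr <- edge_recovery_aucpr(fit$edges, truth)
      out$fdr <- observed_fdr(fit$edges, truth, alpha)
    }
    if (test_n > 0L) out$fit <- fit
    out
  })
  names(res) <- estimators
  if (test_n > 0L) {
    test <- sample_dataset(truth, test_n, seed = seed + 3L)
    Xt <- standardize(cbind(test$X1, test$X2))
    for (est in estimators) {
      res[[est]]$loglik <- gaussian_log_likelihood(res[[est]]$fit$theta, Xt)
      res[[est]]$fit <- NULL
    }
  }
  res
}

#' Default sample-size grid
#'
#' The half-power-of-two ladder `{2^6, floor(2^6.5), 2^7, ...,
#' floor(2^13.5), 2^14}` used by the sample-size scans.
#'
#' @param max_n truncate the grid at this value (default `2^14`).
#' @return integer vector.
#' @export
sample_size_grid <- function(max_n = 16384L) {
  g <- as.integer(floor(2^seq(6, 14, by = 0.5)))
  g[g <= max_n]
}

#' Sample-size scan of edge-recovery performance
#'
#' For each sample size on the grid, runs independent simulation replicates
#' (a freshly generated ground-truth precision matrix and dataset each time),
#' fits the chosen estimator end-to-end (penalty selection, precision,
#' partial correlations, null calibration, p/q-values) and records AUC,
#' average precision, and observed FDR. Summarizes per-n medians and
#' quartiles and reports `minimal_n`, the smallest grid value whose median
#' AUC strictly exceeds `auc_threshold`.
#'
#' @param study a study name (`"A"`..`"D"`) or a [sim_config].
#' @param estimator `"layered"` or `"pooled"`.
#' @param grid integer vector of sample sizes (default [sample_size_grid]).
#' @param reps replicates per sample size (default 20).
#' @param base_seed base RNG seed; replicate `k` at any grid point uses an
#'   independent stride of seeds.
#' @param alpha FDR threshold for the observed-FDR column.
#' @param auc_threshold median-AUC confidence level (default 0.8).
#' @return object of class `"scan_result"`: list with `replicates` (tidy
#'   data.frame), `summary` (per-n medians/quartiles), `minimal_n`,
#'   `p_over_n`, `estimator`, `study`.
#' @export
sample_size_scan <- function(study, estimator = c("layered", "pooled"),
                             grid = sample_size_grid(), reps = 20L,
                             base_seed = 1L, alpha = 0.05,
                             auc_threshold = 0.8) {
  estimator <- match.arg(estimator)
  config <- if (inherits(study, "sim_config")) study else study_config(study)
  label <- if (inherits(study, "sim_config")) "custom" else study
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  rows <- list()
  k <- 0L
  for (n in grid) {
    for (rep in seq_len(reps)) {
      k <- k + 1L
      seed <- base_seed + 1000L * k
      r <- tryCatch(
        .run_replicate(config, n, estimator, seed, alpha)[[1L]],
        error = function(e) {
          warning("replicate failed (n=", n, ", rep=", rep, "): ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        study = label, estimator = estimator, n = n, replicate = rep,
        seed = seed, auc = r$auc, auc_pr = r$auc_pr, fdr = r$fdr,
        lambda1 = r$lambda1, lambda2 = r$lambda2)
    }
  }
  replicates <- do.call(rbind, rows)
  summary <- .scan_summary(replicates, "auc")
  med <- summary$median_auc[match(grid, summary$n)]
  hit <- which(!is.na(med) & med > auc_threshold)
  minimal_n <- if (length(hit)) grid[min(hit)] else NA_integer_
  structure(list(replicates = replicates, summary = summary,
                 minimal_n = minimal_n,
                 p_over_n = (config$p1 + config$p2) / minimal_n,
                 estimator = estimator, study = label,
                 auc_threshold = auc_threshold),
            class = "scan_result")
}

.scan_summary <- function(replicates, value) {
  agg <- function(f, nm) {
    d <- stats::aggregate(replicates[[value]],
                          by = list(n = replicates$n), FUN = f, na.rm = TRUE)
    names(d)[2L] <- nm
    d
  }
  out <- agg(stats::median, paste0("median_", value))
  out[[paste0("q25_", value)]] <-
    agg(function(x, na.rm) stats::quantile(x, 0.25, na.rm = na.rm), "q")$q
  out[[paste0("q75_", value)]] <-
    agg(function(x, na.rm) stats::quantile(x, 0.75, na.rm = na.rm), "q")$q
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat("sample-size scan: study ", x$study, ", ", x$estimator,
      " estimator\n", sep = "")
  print(x$summary, row.names = FALSE)
  cat("minimal n with median AUC > ", x$auc_threshold, ": ",
      x$minimal_n, " (p/n = ", signif(x$p_over_n, 3), ")\n", sep = "")
  invisible(x)
}

#' Paired AUC-difference curve (layered minus pooled)
#'
#' For each sample size, both estimators are fitted to the *same* replicate
#' datasets and the per-replicate AUC difference is summarized by its median
#' and quartiles. Pairing removes the variability due to different simulated
#' precision matrices.
#'
#' @inheritParams sample_size_scan
#' @return list with `replicates` and `summary` data.frames and
#'   `max_median_diff`, the maximum over n of the median paired difference.
#' @export
auc_difference_curve <- function(study, grid = sample_size_grid(),
                                 reps = 20L, base_seed = 1L, alpha = 0.05) {
  config <- if (inherits(study, "sim_config")) study else study_config(study)
  label <- if (inherits(study, "sim_config")) "custom" else study
  rows <- list()
  k <- 0L
  for (n in grid) {
    for (rep in seq_len(reps)) {
      k <- k + 1L
      seed <- base_seed + 1000L * k
      r <- .run_replicate(config, n, c("layered", "pooled"), seed, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        study = label, n = n, replicate = rep, seed = seed,
        auc_layered = r$layered$auc, auc_pooled = r$pooled$auc,
        auc_diff = r$layered$auc - r$pooled$auc,
        aucpr_diff = r$layered$auc_pr - r$pooled$auc_pr)
    }
  }
  replicates <- do.call(rbind, rows)
  summary <- .scan_summary(replicates, "auc_diff")
  list(replicates = replicates, summary = summary,
       max_median_diff = max(summary$median_auc_diff), study = label)
}

#' Paired test-log-likelihood difference curve (layered minus pooled)
#'
#' For each training sample size, both estimators are fitted to the same
#' replicate datasets and their Gaussian log likelihoods are evaluated on a
#' held-out test sample drawn from the same ground truth; the per-replicate
#' difference is summarized by median and quartiles.
#'
#' @inheritParams sample_size_scan
#' @param test_n held-out test-sample size (default 1000).
#' @return list with `replicates` and `summary` data.frames.
#' @export
likelihood_difference_curve <- function(study, grid = sample_size_grid(),
                                        reps = 20L, test_n = 1000L,
                                        base_seed = 1L) {
  config <- if (inherits(study, "sim_config")) study else study_config(study)
  label <- if (inherits(study, "sim_config")) "custom" else study
  rows <- list()
  k <- 0L
  for (n in grid) {
    for (rep in seq_len(reps)) {
      k <- k + 1L
      seed <- base_seed + 1000L * k
      r <- .run_replicate(config, n, c("layered", "pooled"), seed,
                          test_n = test_n, edges = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        study = label, n = n, replicate = rep, seed = seed,
        loglik_layered = r$layered$loglik, loglik_pooled = r$pooled$loglik,
        loglik_diff = r$layered$loglik - r$pooled$loglik)
    }
  }
  replicates <- do.call(rbind, rows)
  list(replicates = replicates,
       summary = .scan_summary(replicates, "loglik_diff"), study = label)
}
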