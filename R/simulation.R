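#' Simulation design for a sparse two-layer precision matrix
#'
#' Describes the ground-truth generator: layer widths, per-block edge numbers
#' (given either as densities `eta` of available positions or as explicit
#' counts), the diagonal-dominance slack, and the measurement-noise standard
#' deviation. Densities are converted to counts with round-half-up, so a
#' design's edge numbers are identical for every seed.
#'
#' @param p1,p2 layer widths.
#' @param densities length-3 vector `c(eta11, eta12, eta22)` of block edge
#'   densities, or `NULL` if `counts` is given.
#' @param counts length-3 integer vector of explicit per-block edge counts
#'   (overrides `densities`).
#' @param diag_epsilon slack added to the dominant diagonal (default 1e-4).
#' @param noise_sd standard deviation of additive Gaussian measurement noise
#'   (default 0.1).
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(p1, p2, densities = NULL, counts = NULL,
                       diag_epsilon = 1e-4, noise_sd = 0.1) {
  if (p1 < 1L || p2 < 1L) stop("layer widths must be positive")
  avail <- c("11" = p1 * (p1 - 1) / 2, "12" = p1 * p2, "22" = p2 * (p2 - 1) / 2)
  if (is.null(counts)) {
    if (is.null(densities) || length(densities) != 3L)
      stop("give either densities (length 3) or counts (length 3)")
    if (any(densities < 0 | densities > 1)) stop("densities must be in [0, 1]")
    counts <- floor(densities * avail + 0.5) # round half up
  } else {
    if (length(counts) != 3L) stop("counts must have length 3")
    densities <- counts / avail
  }
  counts <- as.integer(counts)
  if (any(counts > avail))
    stop("requested edge count exceeds available positions in block ",
         paste(names(avail)[counts > avail], collapse = ", "))
  if (diag_epsilon <= 0) stop("diag_epsilon must be > 0")
  structure(list(p1 = as.integer(p1), p2 = as.integer(p2),
                 densities = stats::setNames(densities, names(avail)),
                 counts = stats::setNames(counts, names(avail)),
                 diag_epsilon = diag_epsilon, noise_sd = noise_sd),
            class = "sim_config")
}

#' Benchmark study designs A-D
#'
#' The four canonical two-layer designs used throughout the package's
#' benchmarks, all with `p1 = 100`, `p2 = 500`, diagonal slack 1e-4 and noise
#' sd 0.1. Studies A-C are defined by block densities
#' (A: 0.05/0.05/0.05, B: 0.05/0.05/0.005, C: 0.05/0.005/0.005), giving
#' 248/2500/6238, 248/2500/624 and 248/250/624 edges respectively. Study D is
#' defined by explicit counts of 500 edges per block (its nominal densities
#' are rounded and would not reproduce the counts exactly).
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return a [sim_config].
#' @export
study_config <- function(name = c("A", "B", "C", "D")) {
  name <- match.arg(name)
  switch(name,
         A = sim_config(100L, 500L, densities = c(0.05, 0.05, 0.05)),
         B = sim_config(100L, 500L, densities = c(0.05, 0.05, 0.005)),
         C = sim_config(100L, 500L, densities = c(0.05, 0.005, 0.005)),
         D = sim_config(100L, 500L, counts = c(500L, 500L, 500L)))
}

#' Generate a sparse two-layer ground-truth precision matrix
#'
#' Four-step recipe: (1) start from the `(p1+p2)`-identity; (2) in each block
#' draw the configured number of off-diagonal positions uniformly at random
#' without replacement and fill each (and its mirror) with an independent
#' Uniform(-1, 1) value; (3) replace every diagonal entry by the sum of
#' absolute values in its row (including the existing diagonal 1) plus
#' `diag_epsilon`, which makes the matrix strictly diagonally dominant and
#' hence positive definite; (4) normalize `theta_ij` by
#' `sqrt(theta_ii * theta_jj)`, so the diagonal becomes exactly 1.
#'
#' @param config a [sim_config].
#' @param seed RNG seed; edge placement and values depend only on this seed
#'   and the config, never on a later sample size.
#' @return object of class `"ground_truth"`: list with `theta` (precision),
#'   `adjacency` (logical), `p1`, `p2`, `config`.
#' @export
generate_precision <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  p1 <- config$p1; p2 <- config$p2; p <- p1 + p2
  theta <- diag(p)
  fill <- function(theta, rows, cols, m, within) {
    if (within) {
      pk <- length(rows)
      pos <- sample.int(pk * (pk - 1) / 2, m)
      # map linear upper-triangle index to (i < j)
      j <- ceiling((1 + sqrt(1 + 8 * pos)) / 2)
      i <- pos - (j - 1) * (j - 2) / 2
    } else {
      pos <- sample.int(length(rows) * length(cols), m)
      i <- ((pos - 1L) %% length(rows)) + 1L
      j <- ((pos - 1L) %/% length(rows)) + 1L
    }
    vals <- stats::runif(m, -1, 1)
    ri <- rows[i]; cj <- cols[j]
    theta[cbind(ri, cj)] <- vals
    theta[cbind(cj, ri)] <- vals
    theta
  }
  i1 <- seq_len(p1); i2 <- p1 + seq_len(p2)
  theta <- fill(theta, i1, i1, config$counts[["11"]], within = TRUE)
  theta <- fill(theta, i1, i2, config$counts[["12"]], within = FALSE)
  theta <- fill(theta, i2, i2, config$counts[["22"]], within = TRUE)
  adj <- theta != 0
  diag(adj) <- FALSE
  diag(theta) <- rowSums(abs(theta)) + config$diag_epsilon
  d <- sqrt(diag(theta))
  theta <- theta / tcrossprod(d)
  nm <- c(paste0("L1_", formatC(i1, width = nchar(p1), flag = "0")),
          paste0("L2_", formatC(seq_len(p2), width = nchar(p2), flag = "0")))
  dimnames(theta) <- list(nm, nm)
  dimnames(adj) <- dimnames(theta)
  structure(list(theta = theta, adjacency = adj, p1 = p1, p2 = p2,
                 config = config, seed = seed),
            class = "ground_truth")
}

#' Sample a noisy dataset from a ground-truth precision matrix
#'
#' Draws `n` observations from `N(0, theta^-1)` and adds independent
#' `N(0, noise_sd^2)` measurement noise to every entry, then splits the
#' columns into the two layers.
#'
#' @param truth a [generate_precision] result.
#' @param n number of samples (>= 2).
#' @param noise_sd noise standard deviation; defaults to the config's value.
#' @param seed RNG seed.
#' @return a [paired_omics] object.
#' @export
sample_dataset <- function(truth, n, noise_sd = NULL, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n < 2L) stop("n must be >= 2")
  if (is.null(noise_sd)) noise_sd <- truth$config$noise_sd
  set.seed(seed)
  p <- ncol(truth$theta)
  U <- chol(truth$theta) # theta = U'U  =>  cov(Z U^-T) has covariance theta^-1
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- t(backsolve(U, t(Z)))
  if (noise_sd > 0)
    X <- X + matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  colnames(X) <- colnames(truth$theta)
  paired_omics(X[, seq_len(truth$p1), drop = FALSE],
               X[, truth$p1 + seq_len(truth$p2), drop = FALSE])
}

#' Three-variable co-regulation toy example
#'
#' A regulator (for instance, a chromatin-state variable from a second omics
#' layer) linearly drives the expression of two genes A and B that have no
#' direct relationship. Marginal correlation between A and B is then large
#' and significant while their partial correlation given the regulator is
#' near zero -- the textbook case for preferring conditional-dependence
#' networks. Default effect sizes and noise are illustrative choices.
#'
#' @param n samples (>= 10).
#' @param effect_a,effect_b linear effect of the regulator on genes A and B.
#' @param noise_sd residual noise standard deviation.
#' @param seed RNG seed.
#' @return list with `data` (n x 3 matrix: regulator, A, B) and
#'   `true_edges` (character matrix of the two true edges).
#' @export
regulator_toy <- function(n = 100L, effect_a = 1.0, effect_b = 1.0,
                          noise_sd = 0.5, seed = 1L) {
  if (n < 10L) stop("n must be >= 10")
  set.seed(seed)
  reg <- stats::rnorm(n)
  A <- effect_a * reg + stats::rnorm(n, sd = noise_sd)
  B <- effect_b * reg + stats::rnorm(n, sd = noise_sd)
  data <- cbind(regulator = reg, A = A, B = B)
  list(data = data,
       true_edges = rbind(c("regulator", "A"), c("regulator", "B")))
}
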