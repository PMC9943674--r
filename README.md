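# shrinknet

Joint Gaussian graphical models for **paired two-layer omics data** — for
instance transcriptome + promoter methylome measured on the same samples —
estimated by **layer-specific covariance shrinkage** with analytically
selected penalties, and scored with a **shrunken-null** significance
calibration. The package targets computational biologists who want a
conditional-dependence (partial-correlation) network across two omics
layers in the usual `p > n` regime, without resampling-based tuning.

## The model

With within/cross-layer covariance blocks `S(k,l)` and diagonal targets
`T(k) = diag(S(k,k))`, the covariance is shrunken block-wise,

    Sigma_hat = [ (1-l1) S11 + l1 T1          sqrt(1-l1) sqrt(1-l2) S12 ]
                [ sqrt(1-l1) sqrt(1-l2) S21   (1-l2) S22 + l2 T2        ]

and inverted to a precision matrix `Theta_hat = Sigma_hat^-1`, giving
partial correlations `rho_ij = -theta_ij / sqrt(theta_ii theta_jj)`. The two
penalties `(l1, l2)` minimize the estimated Ledoit–Wolf risk
`E ||Sigma_hat - Sigma||_F^2`, a closed-form six-term polynomial in
`(l1, l2)` built from moment estimates of the covariance entries — no
cross-validation. `l1 = l2` recovers ordinary single-penalty shrinkage of
the appended data (the layer-agnostic baseline, also provided); `l2 = 1`
decouples layer 2 entirely.

Because shrinkage compresses partial correlations, edge significance uses
the shrunken-null density `f(rho) ∝ ((1-l)^2 - rho^2)^((k-3)/2)` on
`(-(1-l), 1-l)`, with the shape `k` fitted by maximum likelihood on
simulated null data per edge block, followed by per-block
Benjamini–Hochberg adjustment. A simulation generator (sparse two-layer
precision matrices via diagonal dominance) and an edge-recovery benchmark
harness (ROC/PR AUC, observed FDR, sample-size scans, paired difference
curves) are included.

## Worked example

```r
library(shrinknet)

cfg   <- study_config("C")                    # p1 = 100, p2 = 500; 248/250/624 true edges
truth <- generate_precision(cfg, seed = 1)    # sparse ground-truth precision matrix
data  <- sample_dataset(truth, n = 256, seed = 2)

fit <- shrinknet(data, null_seed = 3)
fit
#> shrinknet fit (layered estimator)
#>   n = 256, p1 = 100, p2 = 500
#>   lambda1 = 0.9036, lambda2 = 0.9472
#>   kappa (11/12/22) = 326.4 / 323.8 / 325.3 [empirical]
#>   edges with q < 0.05: 291 of 179700

edge_recovery_auc(fit$edges, truth)           # rank all 179700 pairs vs the truth
#> [1] 0.8634758
observed_fdr(fit$edges, truth)                # false fraction among q < 0.05 calls
#> [1] 0.02749141
```

With only 256 samples for 600 variables, the sparser layer draws the
stronger penalty (`lambda2 > lambda1`), the 291 edges called at `q < 0.05`
are ~97% correct against the known truth, and the full ranking recovers
edges with AUC 0.86. `head(fit$edges)` shows the per-edge table (features,
block, partial correlation, p, q); `write_edge_table()` serializes it.

Real data enter through `read_omics_table()` + `align_samples()` (TSV/CSV,
samples × features), optionally `nonparanormal()` for skewed marginals. A
thin CLI covering fit / simulate / benchmark / null-check lives at
`inst/cli/shrinknet` (see `?run_cli`).

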