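# clusso

Scalar-on-matrix regression for subjects whose matrix-valued predictors have
differing, unordered numbers of rows — the situation produced by
digital-pathology pipelines that segment every tubule (or glomerulus, vessel,
cell, …) on a whole-slide image and compute the same q morphometric features
for each one. Subject *i* contributes a ragged feature matrix
X<sub>i</sub> ∈ ℝ<sup>p<sub>i</sub>×q</sup> and a scalar outcome y<sub>i</sub>
(e.g., eGFR at biopsy); the goal is to predict the outcome and, above all, to
select the features that drive it.

## The method

Averaging all of a subject's objects and running a lasso (the *naive*
approach) discards the mixture structure of the object population — e.g.,
atrophic vs. non-atrophic tubules. **CLUSSO** (CLUstering Structured lasSO)
instead:

1. pools every object across subjects and clusters them into G latent
   subgroups (Gaussian mixture by default, k-means optionally);
2. averages features within subject × cluster and weights each cluster row by
   the subject's observed cluster proportion, giving a balanced design
   X̂<sub>i</sub>\*\* = diag(ŵ<sup>i</sup>) X̂<sub>i</sub>\* ∈ ℝ<sup>G×q</sup>;
3. fits the constrained bilinear ("structured") lasso

   (α̂, β̂) = argmin (1/n) Σ<sub>i</sub> (y<sub>i</sub> − αᵀ X̂<sub>i</sub>\*\* β)² + λ‖β‖₁
   subject to ‖α‖₁ = 1, sign(β₍₁₎) = 1,

   where α holds the cluster (row) effects, β the feature (column) effects,
   and only β is penalized. λ is chosen by 5-fold cross-validation; β̂ is
   L1-normalized and thresholded at 0.001 for selection.

The package also provides the **Full Information** oracle (same criterion on
the true subgroup means and proportions — simulation benchmark), the naive
baseline, an a-priori L1 estimation error bound, synthetic-data generators for
the supported simulation scenarios, and a replication harness computing
TPR/FPR/bias/MSE and clustering accuracy. Fits are returned as S3 objects
with `print`, `summary`, `coef`, `predict`, `fitted`, `residuals` and `plot`
methods; `predict` on new cohorts evaluates every train→test cluster
correspondence and flags the one minimizing test MSE. A thin command-line
wrapper lives in `inst/cli/clusso`.

## Worked example

The package ships a small synthetic cohort (40 subjects, ~12 tubules each,
4 morphometry-style features) generated by its own two-subgroup generator;
the true model uses only `lumen_thickness` (coefficient 4) and
`tbm_thickness` (coefficient 3).

```r
library(clusso)
tub_csv <- system.file("extdata", "synthetic_tubules.csv", package = "clusso")
out_csv <- system.file("extdata", "synthetic_outcomes.csv", package = "clusso")
dat <- load_paired_dataset(tub_csv, out_csv)
fit <- clusso(dat$tubules, dat$outcomes, method = "clusso", G = 2, seed = 1)
summary(fit)
#> CLUSSO (clustering structured lasso)
#>   n = 39 subjects (1 dropped), q = 4 features, G = 2 clusters
#>   lambda = 0.5 (5-fold CV), in-sample MSE = 19.53
#>   selected features (|beta| >= 0.001 after L1 normalization): 4 of 4
#>   cluster (row) effects alpha: 0.5544 0.4456
#>
#> Selected features (L1-normalized coefficients):
#>          feature beta_normalized  magnitude
#>      tubule_area     -0.05947544 0.05947544
#>  lumen_thickness      0.46247033 0.46247033
#>    tbm_thickness      0.41424571 0.41424571
#>  epithelium_area     -0.06380852 0.06380852
```

At this small sample size all four coefficients survive the 0.001 threshold,
but the two truly active features dominate the ranking by almost an order of
magnitude (0.46/0.41 vs. 0.06/0.06); one subject is dropped for lacking a
tubule in one of the two clusters. Predicting with cluster-correspondence
resolution:

```r
predict(fit, dat$tubules, dat$outcomes)
#> Predictions for 39 subjects (2 correspondence permutation(s))
#> Test MSE per correspondence: 19.53, 92.25
#> Chosen correspondence: 1 (1 2)
```

The two MSEs correspond to the two possible matchings of test-set cluster
labels to training-set cluster labels; the smaller one identifies the
operative correspondence.

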