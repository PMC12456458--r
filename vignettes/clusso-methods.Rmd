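---
title: "Scalar-on-matrix regression with unbalanced feature matrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scalar-on-matrix regression with unbalanced feature matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusso)
```

## The problem

Digital-pathology pipelines segment individual objects — in the motivating
setting, renal tubules — from whole-slide images and compute a vector of
morphometric features for each object. Subject $i$ then carries a feature
matrix $X_i \in \mathbb{R}^{p_i \times q}$: $p_i$ objects (rows) that differ in
number across subjects and have no meaningful ordering, and $q$ features
(columns) shared by all subjects. The scientific goal is to regress a scalar
clinical outcome $y_i$ (e.g., eGFR, a measure of kidney function) on these
ragged matrices, and above all to *select* which features carry the signal.

Averaging all of a subject's objects ("the naive approach") collapses each
$X_i$ to a $q$-vector and permits an ordinary lasso, but it erases exactly the
structure that is biologically informative: object populations are typically
mixtures (e.g., atrophic vs. non-atrophic tubules with very different basement
membrane thickness), so a feature's subject-level mean confounds the subgroup
means with the subgroup proportions.

## The model

Assume each object belongs to one of $G$ latent subgroups (the package
defaults to $G = 2$, the setting of interest in nephropathology). For subject
$i$, let $X_i^{*} \in \mathbb{R}^{G \times q}$ hold the subgroup-wise mean
feature vectors and $w^i = (w^i_1, \dots, w^i_G)$ the subgroup proportions.
The weighted design is

$$X_i^{**} = \mathrm{diag}(w^i_1, \dots, w^i_G)\, X_i^{*},$$

and the outcome model is bilinear with row effects $\alpha \in \mathbb{R}^G$
and column (feature) effects $\beta \in \mathbb{R}^q$:

$$y_i = \alpha^{\top} X_i^{**} \beta + \varepsilon_i, \qquad
\varepsilon_i \sim N(0, \sigma^2).$$

Only $\alpha \beta^\top$ is identified: $(\alpha/s, s\beta)$ and
$(-\alpha, -\beta)$ give identical fits. The estimator therefore constrains
$\lVert \alpha \rVert_1 = 1$ and requires the largest-magnitude component of
$\beta$ to be positive, and the fitted criterion penalizes only the feature
effects:

$$(\hat\alpha, \hat\beta) \;=\; \arg\min_{\lVert\alpha\rVert_1 = 1,\;
\mathrm{sign}(\beta_{(1)}) = 1} \;
\frac{1}{n}\sum_{i=1}^n \bigl(y_i - \alpha^{\top} X_i^{**}\beta\bigr)^2
+ \lambda \lVert\beta\rVert_1 .$$

Three fitting strategies share this criterion:

* **Full Information** (oracle): uses the true $X_i^{*}$ and $w^i$ — available
  only in simulation, where it provides the benchmark.
* **CLUSSO**: pools all observed objects across subjects, clusters them into
  $G$ subgroups (Gaussian mixture by default), and replaces $X_i^{*}$ and
  $w^i$ with the within-subject cluster means and observed cluster
  proportions. A subject must have at least one object in *every* cluster;
  otherwise its cluster average is undefined and the subject is dropped (and
  reported). As per-subject object counts grow, the estimated design converges
  to the oracle design, and the CLUSSO solution to the Full Information
  solution; the package tests verify this empirically.
* **Naive**: ordinary lasso on the per-subject feature means.

## The alternating solver

The criterion is biconvex. The solver alternates:

* **$\beta$-step.** With $\alpha$ fixed, $z_i = X_i^{**\top}\alpha$ reduces the
  problem to an ordinary lasso in $\beta$, solved by cyclic coordinate descent
  on the Gram matrix with soft-thresholding (inner tolerance $10^{-9}$ on the
  coefficient change, cap 1000 passes).
* **$\alpha$-step.** With $\beta$ fixed, $v_i = X_i^{**}\beta$. Because any
  $(\alpha, \beta)$ is equivalent to $(\alpha/s,\, s\beta)$ with
  $s = \lVert\alpha\rVert_1$, the constrained criterion profiled over this
  scale class is
  $\frac1n\lVert y - V\alpha\rVert_2^2 + \lambda\lVert\beta\rVert_1
  \lVert\alpha\rVert_1$,
  an L1 problem in $\alpha$ solved by the same coordinate descent. The L1 term
  is purely an artifact of the unit-norm reparametrization — the row effects
  themselves are not regularized. A naively unpenalized least-squares
  $\alpha$-step followed by renormalization would rescale $\beta$ and hence
  the penalty, and can *increase* the objective; the profiled step restores
  the guarantee that the objective is non-increasing at every iteration,
  which the test suite asserts on every recorded trace.
* **Canonicalization.** Each iteration renormalizes
  $(\alpha, \beta) \leftarrow (\alpha/s,\, s\beta)$ (changing neither fit nor
  penalty value); at convergence both vectors are negated if the
  largest-magnitude component of $\beta$ is negative (ties broken toward the
  lowest index). If the profiled $\alpha$ shrinks exactly to zero, the
  canonical equivalent solution $\beta = 0$ is returned.

Iterations stop when the relative objective change drops below `tol`
(default $10^{-6}$) or after `max_iter` (default 200) iterations. Because the
procedure reaches a stationary point rather than a global minimum, fits are
repeated from `n_inits` (default 5) random starts — $\alpha_0$ standard normal
then L1-normalized, $\beta_0$ standard normal — and the best objective wins.
On small instances ($n = 30$, $G = 2$, $q \le 3$) the multi-start solution
matches a brute-force grid over the $\alpha$ L1-sphere (with the convex
$\beta$-lasso solved independently by glmnet at each grid point) to within
$10^{-4}$ relative objective; this dual-route check runs in the test suite.

## Standardization

The model's distributional assumptions on $X^{**}$ (zero mean, unit variance
entries) are met by z-scoring each of the $G \times q$ design cells across
subjects, and centering $y$ instead of fitting an intercept (the model has
none); predictions add the training outcome mean back. The transform is stored
with every fit and applied unchanged to test data. The package standardizes
the final weighted design $X^{**}$ — the quantity that enters the criterion —
rather than $X^{*}$ before weighting, which the model statement leaves open.
Pooled object features are also column-standardized before clustering (a flag
disables this) so that clustering is scale-invariant.

## Choosing the penalty

$\lambda$ is chosen by $k$-fold cross-validation (default 5 folds, seeded
subject shuffle) minimizing held-out squared error over a grid — by default
the linear grid $\{0.5, 1, \dots, 5\}$ used in the simulation study; an
application would typically use a finer, wider grid such as
$\{0.1, 0.2, \dots, 20\}$. Ties go to the smaller $\lambda$ (less shrinkage
when indifferent). Random starts are used inside CV folds as well
(configurable). The naive lasso instead follows the standard
coordinate-descent path convention: 100 log-spaced values from
$\lambda_{\max} = \frac{2}{n}\max_j |\langle \bar x_{\cdot j}, y_c\rangle|$
(the smallest value with an all-zero solution under the $\frac1n$-scaled
criterion) down to $10^{-4}\lambda_{\max}$, fit with glmnet (whose
$\frac{1}{2n}$ convention is rescaled accordingly).

For reporting and selection, $\hat\beta$ is L1-normalized and components with
magnitude below 0.001 are set to zero; the thresholded vector is deliberately
not renormalized. Predictions use the un-normalized solution, since
renormalizing would change the fitted scale.

An a-priori penalty level and L1 estimation error bound are available in
`theoretical_bound()`: $\lambda_n = (1+\delta_0)\sigma\sqrt{2(1+a)\log(Gq)/n}$
and $\lVert\hat\beta - \beta^*\rVert_1 \le 4\kappa^2 \lambda_n s_0
(1 + 2\lVert\beta^*\rVert_1/\beta^*_{(1)})$, where $\kappa^2$ is the
structured restricted-eigenvalue constant supplied by the user and $s_0$ the
support size of $\beta^* \otimes \alpha^*$.

## Clustering back end

The default clustering is a $G$-component Gaussian mixture with unconstrained
component covariances, fit by EM via the mclust package: seeded k-means
initialization (3 starts), then EM to mclust's default relative tolerance.
For very large pooled tables the EM runs on a seeded subsample of at most
25,000 objects — mixture parameters for two components in ten dimensions
stabilize far below that — followed by a single E-step over all objects for
the posterior labels; labels are posterior argmaxes. With matching seeds this
is bit-for-bit reproducible. K-means is available as a model-free
alternative; its ties go to the lowest cluster index. New objects are
classified by the stored standardization and mixture parameters (posterior
argmax; nearest centroid for k-means) without refitting.

When a fitted model is applied to an independent test set, the test-set
cluster labels need not correspond to the training labels (cluster "1" in the
test data may resemble training cluster "2"). `predict()` therefore evaluates
all $G!$ row permutations of the test design and, when test outcomes are
available, flags the permutation with the smallest MSE as the operative
correspondence. By default test objects are labeled with the trained cluster
model (reproducible); independent re-clustering is available via
`recluster = TRUE`.

**Clustering accuracy.** Reported accuracy chooses the single global
permutation of estimated labels (over all $G!$; equivalently Hungarian
matching on the pooled confusion matrix) that maximizes overall agreement
with the truth, then averages the per-subject agreement proportions across
subjects. This convention is deterministic and invariant to relabeling of
either argument.

## The synthetic-data generator

The generator emulates the simulation design the methodology was studied
under; it is first-class, tested code. Per subject:

* **Latent means.** `two_cluster`: rows drawn $N(2, 1)$ and $N(5, 3)$
  entry-wise (here and throughout $N(a, b)$ is mean $a$, *variance* $b$).
  `correlated`: matrix-normal rows with means 2 and 5, row covariance
  $\Sigma_r = \begin{pmatrix}1 & \sqrt3/2\\ \sqrt3/2 & 3\end{pmatrix}$
  (between-row correlation exactly 0.5) and identity column covariance,
  sampled as $\mu + A Z$ with $A A^\top = \Sigma_r$ the lower Cholesky factor.
  `three_cluster`: rows $N(2,1)$, $N(5,3)$, $N(7,3)$ — used to probe
  misspecification when the fit still assumes two clusters.
  `one_cluster`: a single row with entries $N(2, 3)$, under which two-cluster
  fits drop many subjects — diagnostic that clustering is not warranted.
* **Proportions.** $w_1$ uniform on $\{0.2, 0.3, \dots, 0.8\}$ (two-cluster
  scenarios); for three clusters $w_1 \in \{0.2, \dots, 0.6\}$,
  $w_2 \in \{0.2, \dots, 0.8 - w_1\}$, $w_3$ the remainder, so every weight is
  at least 0.2. All finite-set draws are uniform over the set.
* **Coefficients.** Entries of $\alpha^*$ and $\beta^*$ uniform on
  $\{1,2,3,4\}$; `round(s_beta * q)` positions of $\beta^*$ zeroed without
  replacement. One truth (per $q$, sparsity and subgroup count) is shared
  across all settings and repetitions, as in the study design.
* **Outcomes.** $y_i = \alpha^{*\top}\mathrm{diag}(w^i) X_i^{*}\beta^* +
  \varepsilon_i$ with $\varepsilon_i \sim N(0, 1)$ by default; outcome noise
  is redrawn every repetition (only the coefficients are fixed).
* **Observed objects.** Counts $p_i$ are discrete-uniform on $H$ integers
  centered at $\mu_M = 40$, where $H$ is the largest odd integer
  $\le \sqrt{12\sigma_M^2 + 1}$ (variance-matched; $\sigma_M^2 = 5$ gives
  support $\{37, \dots, 43\}$). Each object copies latent row $k$ with
  probability $w^i_k$ and adds $N(0, \sigma_R^2)$ measurement noise
  entry-wise. Larger $\sigma_R^2$ blurs the subgroups: mean clustering
  accuracy decreases from essentially 100% at $\sigma_R^2 = 1$ to roughly 74%
  at $\sigma_R^2 = 46$.

What the generator does *not* emulate: real image features are bounded,
skewed, correlated across features within an object, and object counts in
real biopsies are far larger (hundreds to over a thousand per subject) with
heavy-tailed dispersion. Passing tests on this generator demonstrate
correctness of the estimator under its stated model, not robustness to those
departures.

**Performance metrics.** After thresholding, TPR is the fraction of truly
nonzero $\beta^*$ components estimated nonzero, FPR the fraction of truly
zero components estimated nonzero, and bias the L1 distance between the
component-wise *magnitudes* of the L1-normalized $\hat\beta$ and $\beta^*$
(signs are not identifiable, so magnitudes are compared; this is
configurable in spirit but fixed here). Prediction MSE uses the
un-normalized solution. The harness aggregates medians across repetitions for
all metrics except clustering accuracy, which averages per-repetition subject
means (its distribution across repetitions is tight and symmetric).
Repetition seeds are derived arithmetically from the master seed, so any
setting can be reproduced independently; per-repetition results can be cached
to disk and reruns resume. Metrics with undefined denominators are `NA` and
excluded from medians; failed repetitions are counted, never silently
dropped.

## Numerical and design choices

* Subjects are indexed by sorted `subject_id` everywhere; ordering is
  deterministic given the inputs.
* Model archives are single JSON documents; matrices are stored row-major
  with explicit shapes and doubles with 17 significant digits, so
  write-then-read reproduces every numeric field bit-for-bit.
* Zero-variance design cells (a cluster-feature combination constant across
  subjects) and zero-variance feature columns are fatal, with the offending
  cell or column named.
* A fit in which more than half the subjects are dropped warns and points to
  the naive method: wholesale dropping is evidence the objects do not come
  from $G$ distinct subgroups.
* `G = 1` is supported and collapses, by construction, to a lasso on the
  per-subject means with $|\alpha| = 1$.
* The demonstration data in `inst/extdata` (`synthetic_tubules.csv`,
  `synthetic_outcomes.csv`) are synthetic: 40 subjects, 4 features named
  after tubular morphometry, generated by this package's own two-subgroup
  generator. Real nephropathology cohorts require data-use agreements and are
  not redistributable.

## Problem sizes used in the shipped checks

The test suite and the results-reproduction script run reduced versions of
the study grid chosen to exercise the same contrasts at desk scale: 20
repetitions for the clustering-accuracy summaries at $n = 500$, and 50
repetitions per sample size $n \in \{1100, 1500, 2000\}$ for the
false-positive-rate comparison (the full study used 1000 repetitions per
setting). The qualitative contrasts — near-perfect vs. degraded clustering,
and the naive lasso's rising false positive rate against CLUSSO's flat one —
are stable at these sizes.

## Known limitations

* The criterion is biconvex; multi-start alternating minimization can in
  principle miss the global minimum. The grid-oracle test bounds this risk
  only at small $G$ and $q$.
* Signs of $\alpha$ and $\beta$ are not identifiable; only magnitudes (and
  the sign pattern within $\beta$ up to a global flip) should be
  interpreted.
* Subjects lacking an object in some cluster are dropped, not imputed; with
  small $p_i$ and unbalanced proportions this loses data, and the dropped
  fraction should always be inspected (it is stored on every fit).
* Model selection of $G$ is out of scope; $G$ is fixed by the analyst.
* Continuous outcomes only; binary or survival outcomes would require a
  different loss.
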