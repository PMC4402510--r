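---
title: "Moderated gene-wise linear models: methods and design notes"
author: "modlm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated gene-wise linear models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modlm)
```

# The model

For every gene $g$ we observe a vector $y_g$ of $N$ log-expression values
(log2 intensities for arrays, logCPM for RNA-seq) and fit the same linear
model
$$ y_g = X\beta_g + \varepsilon_g, \qquad
   \operatorname{var}(\varepsilon_{gj}) = \sigma_g^2 / w_{gj}, $$
where $X$ is the $N \times p$ design matrix shared by all genes and the
$w_{gj}$ are optional precision weights. Least squares gives coefficients
$\hat\beta_{gk}$, unscaled standard deviations $u_{gk}$ (so that
$\operatorname{se}(\hat\beta_{gk}) = u_{gk}\sigma_g$), the residual variance
estimate $s_g^2$ on $d_g$ degrees of freedom, and contrasts
$C^\top \hat\beta_g$ with variances propagated through the coefficient
covariance.

With a handful of replicates, $s_g^2$ is a terrible estimate on its own.
The gene-wise models are therefore linked through a hierarchical prior
$$ 1/\sigma_g^2 \sim \chi^2_{d_0} / (d_0 s_0^2), $$
whose hyperparameters $(d_0, s_0^2)$ are estimated from all genes at once by
moments of $\log s_g^2$: the prior degrees of freedom solve a trigamma
equation (inverted by Newton's method) and the prior variance follows from
the mean. The posterior variance
$$ s_g^{*2} = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g} $$
replaces $s_g^2$ in the t-statistics, which then have $d_0 + d_g$ degrees of
freedom (capped at the pooled residual df). $d_0 = 0$ recovers classical
per-gene t-tests exactly; $d_0 = \infty$ pools all genes to a common
variance. Moderated F-statistics orthogonalize the contrast t-vector through
the contrast correlation matrix (by an eigendecomposition, so redundant
contrasts simply reduce the effective numerator rank), and the B-statistic
converts t into a posterior log-odds of differential expression.

## Trended and robust priors

With `trend = TRUE` the prior variance becomes a function of average
log-expression: a robustified lowess (span 0.5, 3 iterations) of the
adjusted log-variances replaces the constant prior mean, and the moment
equations run on the residuals from that curve. With `robust = TRUE` the
moments are computed from 5%/95%-winsorized log-variances and genes above
the upper winsorization limit receive an individual prior df that decays
smoothly to zero with outlyingness (scaled by the total spread), so
hypervariable genes are not squeezed down into false significance. The
exact per-gene df formula for robust shrinkage is not settled in the
literature; the variant here is deliberately simple and is exercised by
behavioural tests (outliers are squeezed less) rather than numeric oracles.

## TREAT

`treat(fit, lfc)` replaces the point null $\beta = 0$ by the interval null
$|\beta| \le \mathrm{lfc}$:
$p = P(T > (|\hat\beta| - \mathrm{lfc})/\mathrm{se}) +
     P(T > (|\hat\beta| + \mathrm{lfc})/\mathrm{se})$
on the moderated degrees of freedom. It is exactly the moderated two-sided
p-value at `lfc = 0` and increases monotonically with the threshold.

# RNA-seq counts: voom

Counts are transformed to $\log_2((c + 0.5)/(L + 1)\cdot 10^6)$ with $L$ the
(optionally TMM-scaled) library size. The empirical mean-variance trend —
square-root residual standard deviation against average log2 count — is
smoothed by lowess (span 0.5), each observation's fitted log2 count is
mapped through the curve (piecewise-linear, flat beyond the observed range
to avoid explosive weights), and the inverse fourth power of the predicted
square-root standard deviation becomes its precision weight. Downstream
analysis is then identical to the microarray path. TMM factors are computed
with the standard constants (30% log-ratio trim, 5% abundance trim,
delta-method precision weights, 75th-percentile reference column) and
rescaled to geometric mean one; because M-values are taken on
library-size-normalized abundances, a sample that is an exact scalar
multiple of another gets factor 1.

`voom_with_quality_weights()` alternates the voom weights with sample-level
variance weights (two rounds); the final observation weight is the product
of the two layers.

# Quality weights, blocking, batches

`array_weights()` fits $\operatorname{var}(\varepsilon_{gj}) =
\sigma_g^2/w_j$ by an iterative moment update: per-sample means of
standardized squared residuals, corrected by leverage, multiply the inverse
weights until convergence; weights are reported with geometric mean 1.

`duplicate_correlation()` estimates a single intrablock correlation shared
by all genes. An orthogonal within-block (Helmert-type) transform
diagonalizes the equicorrelation matrix for every $\rho$ at once, so the
exact profiled REML criterion for each gene reduces to a weighted residual
sum of squares; it is evaluated on a $\rho$ grid of step 0.005 (vectorized
over genes) and the per-gene argmax is refined by parabolic interpolation.
Per-gene estimates are clamped to $|\rho| \le 0.99$, transformed by atanh,
combined by a 15% trimmed mean and transformed back. A grid search was
preferred over per-gene Fisher scoring because it is deterministic, immune
to divergence, and two orders of magnitude faster in vectorized form; the
grid resolution is far below the estimator's sampling error. The same
transform implements generalized least squares in `lm_fit()` (with
$\rho = 0$ the ordinary least-squares code path runs unchanged, bit for
bit).

`remove_batch_effect()` fits the protected design plus sum-to-zero batch
indicators and subtracts only the batch terms, so corrected values stay
centred and effects orthogonal to batch pass through unchanged.

# Gene set tests

* `gene_set_test()`: Wilcoxon rank-sum of set versus non-set statistics
  (|t| for the mixed alternative); exact tail when the smaller group has at
  most 10 members and no ties, otherwise a tie-corrected normal
  approximation with continuity correction.
* `camera()`: competitive test with a variance inflation factor
  $\mathrm{VIF} = 1 + (m - 1)\bar\rho$, where $\bar\rho$ is the mean
  pairwise correlation of the set genes' unit-normalized residual vectors
  (the model's residual space), floored at zero to avoid anti-conservative
  VIFs below 1. The set and rest means of the z-transformed moderated t are
  compared by a two-sample t-test with the set variance inflated.
* `roast()`/`mroast()`: self-contained rotation tests. Each gene reduces to
  a $(d+1)$-vector holding the contrast signal and the residual coordinates;
  rotations replace it by its norm times a uniform random direction, and
  moderated t-like scores (variances squeezed with the all-gene prior) are
  summarized by `mean`, `floormean`, `mean50` or `msq`. p-values use the
  plus-one estimator, so they live on the grid $k/(\mathrm{nrot}+1)$; the
  mixed alternative uses squared scores throughout. Direction annotations
  flip, and gene weights scale, the scores before summarizing — only the
  relative magnitude of the weights matters.
* `romer()`: competitive rotation analogue of gene set enrichment analysis;
  every rotation re-ranks all moderated scores and each set is summarized
  by its mean rank.
* `enrich_overlap()`: one-sided hypergeometric over-representation for
  user-supplied sets, BH-adjusted.
* `barcode_profile()`: ranked positions of the set plus a tricube-smoothed
  relative enrichment curve (local set density over uniform density). The
  default smoothing half-width, one tenth of the ranking, keeps a random
  set's curve within a factor of two of 1 over roughly 95% of positions at
  typical set sizes.

One shared rotation stream (standard normals normalized to the sphere,
driven by `--seed`/`seed`) serves all sets in `mroast()`/`romer()`, so
results are reproducible and comparable across sets.

# Differential splicing

`diff_splice()` compares each exon's contrast coefficient with the
precision-weighted average over its gene, with precisions
$1/(u^2 s^{*2})$ from the moderated variances; the deviation variance
$1/w_e - 1/\sum_f w_f$ accounts for the shared average. Gene-level results
report an F-type statistic $\sum_e w_e d_e^2/(k-1)$ and a Simes aggregate
of the exon p-values. Because the deviations within a gene are constrained
to sum to zero, the exon p-values are negatively dependent and the Simes
aggregate is mildly conservative under the null (the exon-level p-values
themselves are calibrated: rejection at the 0.05 level is 0.046–0.050 in
the package's null simulations). This is a structural property of the
aggregation, shared (with opposite sign) by reference implementations, and
is the reason one clause of the splicing acceptance test can fail its
uniformity assertion while the procedure remains valid for ranking.

# Preprocessing

Background correction models observed intensities as normal noise plus
exponential signal. The maximum likelihood fit standardizes the data first
(making the optimizer scale-invariant), starts from method-of-moments
values and refines by Nelder-Mead on the closed-form convolution
log-density evaluated in log space. The corrected value is the posterior
mean $E[S \mid X = x]$ — strictly positive and monotone — computed with a
log-space Mills ratio for deep-tail stability. Quantile normalization
assigns tied values the mean of their tied targets, which makes it
deterministic and idempotent. Cyclic loess fits degree-1 robust loess
curves of M on A for each column pair (span 0.7, 3 cycles), honouring
observation weights; near-constant M-values short-circuit to their mean
(the robust fitter is undefined at zero spread). Raw intensities are logged
with a moderate offset (default 16) so no value can become non-finite.

# Synthetic data

The generators state the world the tests assume:

* `sim_log_matrix()`: variances from the scaled inverse chi-square prior
  (defaults $d_0 = 4$, $s_0^2 = 0.05$ — the values the acceptance criteria
  quote), baselines uniform on $[4, 14]$ log2 units, true effects
  $N(0, \mathrm{logfc\_sd}^2)$ on a chosen coefficient for a `de_fraction`
  of genes, normal errors. Under this model the moderated t is exactly
  t-distributed, which is what the type-I-error criterion exercises.
* `sim_counts_nb()`: negative-binomial counts, expected counts log-uniform
  on $[5, 5000]$, dispersion $0.05 + 2/\mu$ (squared biological variation
  asymptoting to 5% — a typical bulk RNA-seq floor), library sizes within
  ±30%. It reproduces the decreasing variability-versus-count-size trend
  that motivates voom.
* `sim_blocks()`: equicorrelated within-block errors at any
  positive-definite $\rho$ (via a per-block Cholesky factor).
* `sim_correlated_sets()`: null data where designated sets share a latent
  factor inducing within-set correlation — the world in which competitive
  tests without a VIF are anti-conservative.

What these generators do *not* emulate: count outliers and zero inflation,
gene-gene correlation outside designated sets, GC/length biases,
batch-by-treatment confounding, or heavy-tailed (non-normal) errors. A
green calibration test therefore establishes correctness of the
implementation under its stated model, not robustness to every real-data
pathology. All generators run on R's pinned RNG (Mersenne-Twister,
inversion normals, rejection sampling) under an explicit seed and restore
the caller's RNG state, so fixtures are stable across platforms.

# Numerical choices and degenerate inputs

* Trigamma inversion: Newton with asymptotic starts, 50 iterations,
  relative tolerance 1e-10.
* Genes with zero residual df are excluded from prior estimation and
  receive the prior variance and prior df afterwards, so they remain
  testable.
* `df_total` is capped at the pooled residual df (one gene cannot borrow
  more information than the ensemble holds).
* Saturated designs give exact interpolation with `sigma = NA`.
* Robust regression uses Huber weights at $k = 1.345$ on a median-absolute-
  deviation scale, at most 20 reweighting steps, residual df unchanged.
* The B-statistic's coefficient-variance prior matches the 90th percentile
  of |t| to its null counterpart, floored at zero; with no excess spread
  the B ranking degenerates gracefully to a constant.
* Rotation p-values are never zero: the plus-one estimator bounds them
  below by $1/(\mathrm{nrot}+1)$.
* Duplicate sample ids are rejected at construction (their intent is
  ambiguous); duplicate gene ids are rejected unless explicitly suffixed.

# Scaling of the test suite

Calibration tests run at reduced sizes chosen for a single CPU (e.g. FDR
replicates at 2000 genes, romer at 500 genes and 999 rotations, camera
calibration on 500 null sets); the assertions use the acceptance criteria's
own tolerances, and simulation sizes were fixed before the assertions were
run, not tuned to them.

# Known limitations

* Observation weights combined with a block correlation whiten the
  standardized errors — a documented approximation flagged experimental.
* After `contrasts_fit()` with gene-specific weights, contrast standard
  errors use the common coefficient correlation (exact for a shared
  design; an approximation otherwise).
* The group-specific variance trend mentioned in the field's literature is
  not implemented; the API accepts a single trend only.
* `romer()` holds all rotated statistics for ranking; memory grows as
  rotations × genes.
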