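---
title: "Kernel-weighted local polynomial regression for QSAR/QSAAR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-weighted local polynomial regression for QSAR/QSAAR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kwlpr)
```

## The model

Global regression models — multiple linear regression above all — remain the
workhorse of QSAR and interspecies QSAAR modeling, but they impose one
functional form on the whole descriptor space. Kernel-weighted local
polynomial regression replaces the global fit with a separate weighted
least-squares fit at every query point: a Taylor-expansion view of the
unknown response surface $m(x)$ says that near a point $x_0$ it is well
approximated by a low-degree polynomial, so we solve

$$\min_\beta \sum_{i=1}^{n}\Big\{y_i-\sum_{j=0}^{p}\beta_j (x_i-x_0)^j\Big\}^2\,
K\!\Big(\frac{x_i-x_0}{h}\Big),$$

whose weighted least-squares solution is
$\hat\beta = (X^\top W X)^{-1}X^\top W y$ with
$W=\mathrm{diag}\{K((x_i-x_0)/h)\}$. The prediction at $x_0$ is the local
intercept $\hat\beta_0$. Only compounds chemically close to the query (as
measured on the auto-scaled descriptor scale) influence its prediction.

Two degrees are supported and deliberately no more: $p=0$, the
local-constant (Nadaraya–Watson) kernel-weighted average, and $p=1$, the
local-linear estimator. Higher-degree local polynomials reduce bias at peaks
and valleys but extrapolate erratically — a serious liability in QSAR use,
where new compounds routinely sit near or beyond the edge of the training
domain. Low-order fits extrapolate roughly linearly and degrade gracefully.
With several descriptors, $p=1$ uses additive first-order terms (one slope
per descriptor, no cross terms), the standard multivariate local-linear
form; the printed normal-equation formula is the contract, while the
implementation solves the (ridge-guarded) normal equations directly.

### Kernels and multivariate weighting

Three kernels are provided: Gaussian $(2\pi)^{-1/2}e^{-u^2/2}$, Epanechnikov
$0.75(1-u^2)\,\mathbf{1}_{|u|\le1}$ and uniform $0.5\,\mathbf{1}_{|u|\le1}$.
Kernel choice has a second-order effect on accuracy; support matters more:
compactly supported kernels can leave a query with an empty neighborhood,
which this package treats as an explicit error advising a larger bandwidth
or the Gaussian kernel, never as a silent `NA`. Multivariate weights are
independent products $w_i=\prod_j K\{(x_{ij}-x_{0j})/h_j\}$ with one
bandwidth per descriptor — matching how per-descriptor bandwidths are
reported in applied KwLPR work — rather than a full bandwidth matrix.
Normalisation constants are kept so printed weights are comparable across
implementations (they cancel in the estimator).

### Auto-scaling

All localization happens on standardized descriptors: training-split means
and sample (n−1) standard deviations are fitted once and applied to every
row, validation compounds included, so no information leaks from the
validation set into the model. Bandwidths are interpreted on this scaled
scale, where fixed search bounds are meaningful across datasets.

## Bandwidth selection

The bandwidth vector $h$ controls the bias–variance trade-off: small $h$
overfits (high variance), large $h$ underfits (high bias). Three selectors
are implemented, all returning a constant (non-adaptive) bandwidth:

* **`cv.ls`** — least-squares cross-validation, minimizing
  $CV(h)=n^{-1}\sum_i\{y_i-\hat m_{-i}(x_i)\}^2$. Because both estimators
  are linear smoothers, the leave-one-out value is computed exactly from the
  in-sample fit via the deletion identity
  $\hat m_{-i}(x_i) = (\hat m(x_i)-H_{ii}y_i)/(1-H_{ii})$; rows where the
  identity degenerates numerically ($1-H_{ii}\le 10^{-4}$) are refitted
  literally, and rows whose leave-one-out neighborhood is empty contribute a
  large finite penalty ($4\,\mathrm{var}(y)$, a squared-range scale) so the
  objective stays total and optimizable.
* **`cv.aic`** — the Hurvich–Simonoff–Tsai corrected AIC for nonparametric
  smoothers, $\log\hat\sigma^2 + \{1+\mathrm{tr}(H)/n\}/\{1-(\mathrm{tr}(H)+2)/n\}$,
  the standard concrete form of expected Kullback–Leibler cross-validation
  for linear smoothers; it returns $+\infty$ once $\mathrm{tr}(H)+2\ge n$,
  an explicit overfitting barrier.
* **`plugin`** — the Ruppert–Sheather–Wand direct plug-in selector for
  univariate local-linear Gaussian regression, delegated to
  `KernSmooth::dpill()` (blocked-quartic pilot estimates of curvature and
  residual variance plugged into the asymptotically optimal rate formula),
  clamped to the search bounds; an exactly linear response degenerates the
  curvature functional, and the selector then returns the upper bound with
  a warning. It is refused (with a pointer to the CV methods) for
  multivariate problems or the local-constant estimator.

The CV objectives are minimized by bounded multistart L-BFGS-B on
$\log h$ over a default box of $[0.05, 5]$ (scaled scale) with 5 restarts:
the first start is the geometric center of the box, the rest are drawn
uniformly in the log box from the user's seed, and both box corners are
evaluated as a safeguard, so every selection is a pure function of (data,
method, bounds, restarts, seed). The optimizer, restart policy and bounds
are this package's own choices; other valid local minima exist, which is why
the replication mode below fixes bandwidths instead of re-selecting them.

## The validation panel

`kw_validate()` assembles the conventional QSAR quality panel at full
precision (the print method rounds to two decimals):

* calibration: $R^2$ and RMSE (denominator $1/n$ throughout, for consistency
  across the calibration/cross-validation/prediction variants);
* internal: $Q^2_{LOO}$ and RMSE$_{CV}$ from leave-one-out over the training
  split with **bandwidths held fixed** — re-selecting per fold would measure
  bandwidth stability, answer a different question and cost $n$ times more;
* external: $Q^2_{F1}$ (reference: training mean), $Q^2_{F2}$ (validation
  mean), $Q^2_{F3}$ (training variance per observation), Lin's concordance
  correlation coefficient in its original population-moment form, RMSE$_P$
  and MAE. With no validation rows these are reported as `NA`, never zero.

$r_m^2$-type metrics and Golbraikh–Tropsha checks are out of scope.

## Applicability domain

The Williams-plot convention: leverages $h_i=u_i^\top(U^\top U)^{-1}u_i$
from the global design matrix $U=[1\,|\,\text{scaled descriptors}]$ of the
training split, validation rows scored against the training normal matrix
without refitting (so a new compound's domain membership is assessable
before prediction). The critical leverage is $h^*=3(d+1)/n_{train}$;
residuals are standardized by the training RMSE for both splits with a
$\pm3$ band. Flags use strict inequalities: a point exactly on a boundary is
not an outlier. The regression model itself is nonparametric, but domain
analysis by leverage is deliberately model-agnostic — it describes where the
training data are, not what the smoother does there. An essentially
interpolating model (calibration RMSE below $10^{-10}$ of the response
range) has no residual scale and standardization is refused explicitly.

## Y-scrambling

`y_scramble()` permutes the training responses (descriptors and validation
rows untouched), refits with the same degree, kernel and fixed bandwidths,
and records each scrambled model's $R^2$ and $Q^2_{LOO}$. Permutation $k$
draws its RNG stream from `seed + k`, so results are independent of
execution order; the identity permutation is injected as permutation 0 and
must reproduce the unscrambled statistics exactly. The summary statistic is
the empirical p-value (fraction of permuted $R^2$ at or above the true
$R^2$); fit failures are counted and skipped, never imputed. Bandwidths are
not re-selected per permutation: at the conventional 500 permutations that
would multiply cost five-hundred-fold and again answer a different question.

## Interpretation

A local model has no single global equation, so interpretation is post hoc:
PCA on the correlation matrix of the auto-scaled modeling variables, with
loadings reported on the correlation scale (eigenvector × √eigenvalue), so
each loading is exactly the Pearson correlation between a variable and a
component — verified numerically in the tests. The modeled response is
included among the variables by default (so the endpoint trend is readable
from the biplot), with a flag for descriptors-only analysis, covering both
readings of common practice. Component signs are fixed by making each
component's largest-magnitude loading positive, making output deterministic
and row-order invariant. `biplot_notes()` turns PC1/PC2 loading angles into
the conventional textual reading (adjacent angle ⇒ positive association,
right angle ⇒ none, straight angle ⇒ negative).

## Synthetic data: what it emulates, what it does not

`generate_fixture()` provides the package's seeded test beds:

* `sine1d` — one descriptor, $y=\sin x$ on $[0,2\pi]$ plus Gaussian noise,
  default noise sd $\sqrt{0.5}/3$, i.e. signal-to-noise 3:1: the canonical
  smooth nonlinear curve for which oversmoothing and overfitting are both
  visible.
* `linear1d` — exact affine truth $y=2x+1$, noise-free by default, used for
  the polynomial-reproduction guarantee of the local-linear estimator.
* `qsaar2d` — the study-shaped table: descriptors `LogP`
  $\sim N(3, 1.5^2)$ and `pEC50` $\sim N(4, 1.2^2)$ with correlation 0.5
  (interspecies descriptor pairs are typically moderately correlated,
  $r\approx0.5$), response
  $0.27+0.17\,\mathrm{LogP}+0.67\,\mathrm{pEC50}+0.8\tanh\{1.5(\mathrm{LogP}-3)\}$
  plus noise sd 0.6 — a dominantly linear surface with a material smooth
  saturation, so a global linear fit calibrates around $R^2\approx0.83$
  while the local model can do visibly better, the regime KwLPR is for.
  Defaults 254 training / 64 validation compounds, a realistic pesticide
  dataset size. The linear coefficients echo published interspecies
  pesticide models; the saturation term and its scale are this package's
  choice.
* `noise_only` — response independent of descriptors, the null model for
  Y-scrambling behavior.

Each fixture carries its ground-truth function as an attribute, enabling
recovery tests against the noise-free signal. What the generators do **not**
emulate: heavy-tailed experimental error, censored endpoints, descriptor
measurement error, activity cliffs, cluster structure from chemical series,
or class-imbalanced splits. Passing tests therefore demonstrate estimator
and workflow correctness under clean conditions, not performance on any
real chemical dataset.

## Numerical choices and degenerate inputs

* Normal equations: direct solve; on singularity or non-finite results a
  ridge term of $10^{-8}$ × mean diagonal of $X^\top WX$ is added and the
  solve retried; persistent failure is an explicit numerical error. This
  matters for the local-linear estimator in sparse neighborhoods.
* Empty neighborhoods (all weights zero, compact kernels): explicit error
  in prediction, carrying the row index; large finite penalty inside the CV
  objective; per-row exclusion with a count in LOO metrics.
* Missing values are rejected with row/column named — silently dropping rows
  would corrupt the reported training/validation counts.
* Zero-variance descriptors are rejected at scaling, by name.
* Split labels are normalized case-insensitively
  ({train, training, t} / {valid, validation, test, v}) to tolerate
  hand-edited files.
* Rounding is display-only; all stored and written values keep full
  precision (summary CSVs print 15 significant digits).

## The replication mode

For checking a published KwLPR model, `run_grid(..., fix_bandwidth = )`
skips selection and evaluates the model at the printed per-descriptor
bandwidths with the printed estimator and kernel on auto-scaled descriptors,
producing the full panel plus per-compound artifacts from which every
summary number can be re-derived (`report_from_predictions()`). Published
tables do not always state whether bandwidths are on the raw or the
auto-scaled variable scale; this package fixes their meaning to the scaled
scale (published values around 0.2–0.8 are consistent with scaled
variables), and the raw reading can be reproduced by dividing the printed
values by the training standard deviations before fixing them.

## Problem sizes used in the test suite

The suite exercises the estimator oracles on hundreds of random instances
with $n\le20$, $d\le3$; cross-validation oracles at $n\le30$ over 30-point
bandwidth grids; workflow tests on fixtures of 30–100 compounds; and the
study-shaped 254/64 table for the end-to-end panel, domain analysis and
100-permutation scrambling runs. These sizes keep the whole suite fast
while covering every code path; nothing in the implementation is specific
to them.

## Known limitations

* No adaptive/variable bandwidth $h(x)$; constant bandwidths only.
* Degrees above 1, derivative estimation and confidence bands are out of
  scope.
* The plug-in selector is univariate local-linear Gaussian only, by
  construction of the method.
* LOO with compact kernels can be undefined for isolated compounds; such
  rows are excluded and counted rather than imputed.
* Bandwidth selection is a non-convex optimization; different
  optimizer/restart policies can land in different valid local minima, which
  is precisely why published-model replication fixes bandwidths.
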