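---
title: "Cross-tissue transcriptome imputation: models, evaluation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue transcriptome imputation: models, evaluation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstx)
```

## The problem and the model

Lung tissue is rarely available for transcriptomic study of non-cancerous
lung disease, while blood RNA-seq exists at cohort scale. `crosstx` predicts
target-tissue expression from blood using principal-component regression
trained on a paired cohort: blood profiles (samples as observations, genes as
features) are standardized per gene and reduced to the top $K$ right singular
vectors; each target-tissue gene $i$ is then modeled as

$$Y_i = \beta_0 + \beta_1 X_1 + \dots + \beta_K X_K + \varepsilon,$$

with $X_1,\dots,X_K$ the blood component scores and the coefficients fit by
ordinary least squares. The approach assumes that whatever target-tissue
signal is predictable from blood flows through broad covariation patterns
mixed across many blood genes — latent physiology, cell-type composition,
systemic state — rather than through any single blood transcript. OLS rather
than a penalized fit is used because the predictors are few ($K \le 40$),
orthogonal by construction, and far outnumbered by training subjects, which
removes the usual motivation for shrinkage.

## Evaluation: cross-validation, selection, replication

Per-gene predictive accuracy is estimated by $k$-fold cross-validation
(default $k = 5$) with folds assigned at the *subject* level so paired
samples never straddle a split, and with the PCA **and** all gene models
refit inside every training split — scores computed once on all data would
leak the held-out subjects into training. Accuracy is reported two ways:

* `mean_fold_r` / `mean_fold_r2`: the per-fold Pearson correlation between
  observed and predicted expression (and its square), averaged over folds —
  the accuracy point estimate;
* `pooled_r`: the correlation over the concatenated out-of-fold predictions,
  whose two-sided $t$-test p-value ($t = r\sqrt{(n-2)/(1-r^2)}$, $n-2$ df)
  feeds Benjamini–Hochberg adjustment across genes — one well-powered test
  per gene instead of five fragmentary ones.

$R^2$ here is the *squared correlation* of observed and predicted values,
not $1 - \mathrm{SSE}/\mathrm{SST}$: the replication threshold $r \ge 0.1$
and the selection threshold $R^2 \ge 0.01$ are consistent only under that
reading. A gene is selected when `mean_fold_r2 >= 0.01`, `q <= 0.05`
(both inclusive) and — an extension that can be toggled off with
`require_positive = FALSE` — `pooled_r > 0`, since a squared criterion would
otherwise admit systematically anti-correlated predictions.

Replication against an independent paired cohort compares the training
pooled correlation with the replication correlation per gene using the
Fisher-z transform, $z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)\,/\,
\sqrt{1/(n_1-3) + 1/(n_2-3)}$. A gene replicates when $p > 0.05$ (strict;
uncorrected by design — correction would make replication *easier* as the
gene count grows) and the replication $r \ge 0.1$ (inclusive). The training
$n$ used in the test is the full training cohort size, the number of
subjects contributing pooled out-of-fold predictions; it is recorded in the
output for transparency.

## Normalization stages

The counting-scale utilities follow standard bulk RNA-seq practice:

* **CPM** uses the full column sum, computed *before* any gene filtering, as
  the library size: filtering order must not change what "per million" means.
* **Low-expression filter**: a gene is dropped when CPM $\le$ 1 in at least
  100 samples (both tunable).
* **log2** adds a pseudocount of 1 by default, since zeros are ubiquitous in
  CPM; the pseudocount is a visible argument, not a hidden constant.
* **Quantile normalization** substitutes per-rank means of the sorted
  columns; ties receive the mean of the target values over their tied ranks,
  a deterministic rule implemented directly (interpolation at the average
  tied rank, as some implementations do, differs for three-way-or-wider ties).
* **TMM factors** implement the trimmed-mean-of-M-values estimator with the
  canonical 30%/5% two-sided trims on M and A, precision weights from the
  approximate binomial variance, reference selection by the upper quartile of
  library-scaled counts, and a geometric-mean-1 rescaling. The implementation
  is validated in the test suite against `edgeR::calcNormFactors` to a
  relative 1e-10 on random count matrices.
* **Batch adjustment** is a deliberate simplification: per gene, each batch
  is standardized to the gene's pooled mean and SD (mean-centering only where
  a batch is degenerate). It equalizes batch location and scale and preserves
  within-batch ranks, but applies no empirical-Bayes shrinkage across genes;
  with few samples per batch its variance estimates are accordingly noisier
  than a shrinkage method's.

## The simulator: what it emulates, and what it does not

`simulate_paired()` generates the study conditions for every stage: subjects
carry `n_factors` standard-normal latent factors shared by both tissues; a
blood gene is a unit-norm loading combination of the factors plus Gaussian
noise (default `noise_sd = 1`, i.e. half of each blood gene's variance is
factor signal — enough noise that factor recovery is a real task, while a
realistic transcriptome-scale gene panel still supports accurate PCA); a
target-tissue gene draws exactly a fraction $f$ of its unit variance from the
factors and $1-f$ from private noise. $f$ is therefore each gene's
*imputability*, with the analytic ceiling $\mathbb{E}[r] \le \sqrt f$ on any
blood-based predictor. Default study sizes in the tests — 300 paired
subjects, 300–500 blood genes, $f$-blocks at $\{0, 0.05, 0.2, 0.5\}$ — were
chosen to represent paired-cohort studies at a few hundred subjects while
keeping each test self-contained and fast; they are stated in each test.

`simulate_case_control()` adds case shifts by two routes. `shared_factor`
shifts the cases' latent factors by the minimum-norm vector reproducing the
requested target-tissue log2 fold changes, so blood carries a mixed,
sign-scrambled, attenuated trace and imputation *can* recover the effect;
with more effect genes than factors the system is overdetermined and the
realized (least-squares) effects — recorded per gene in the returned truth —
are attenuated, so tests use at most `n_factors` effect genes. Because the
loadings are dense, the factor shift also spills small effects into
non-effect genes; the truth records the realized value for every gene.
`lung_private` shifts only target-tissue residuals, so imputation cannot see
the effect — the contrast that separates what imputed-tissue differential
expression can and cannot recover. Metadata (age uniform on 45–70, sex,
batch, leukocyte percentages, FEV1/FVC consistent with status) is drawn
independently of expression, so covariates are unconfounded by default.

`simulate_counts()` provides negative-binomial count matrices (log-normal
gene means, uniform library multipliers) for the counting-scale operations.

What the simulator does **not** emulate: mean–variance relationships of real
log-expression, heavy-tailed and zero-inflated genes, structured (cell-type)
covariance beyond generic dense factors, batch effects entangled with
biology, or any nonlinearity between tissues. Passing tests therefore
demonstrate correctness of the algorithms and calibration under the stated
generative model — not that any particular accuracy will be achieved on real
cohorts.

## Numerical and design choices

* Genes are z-scored (not merely centered) before PCA so highly expressed
  genes cannot dominate components; the stored per-gene means/SDs make
  projection of new samples well-defined. Centering-only is available via
  `scale. = FALSE`.
* Component signs are fixed by making each component's largest-magnitude
  loading positive, so saved bundles are reproducible across platforms.
* At projection time, genes missing from the new data contribute 0 after
  standardization (the training mean), with a hard 50% coverage floor —
  graceful degradation with an explicit guardrail.
* $K$ must not exceed the numerical rank of the standardized training matrix
  (singular values below `max(d) * 1e-8 * max(dim)` are treated as zero);
  requesting more components than the data support is an error, not a
  silently degenerate fit.
* Zero-variance genes are dropped with a warning before PCA, skipped with a
  record in per-gene model training, and flagged (not errored) in per-gene
  correlation computations inside larger procedures.
* Correlations are clamped to $[-1, 1]$ against floating-point overshoot
  before the $t$-transform; $|r| = 1$ saturates to $p = 0$ rather than NaN.
* Duplicate gene IDs after version stripping keep the highest-mean row, with
  a warning — deterministic and common practice. Missing values are rejected,
  never imputed: the method defines no missing-data handling.
* FDR is computed from the pooled out-of-fold correlations (one p-value per
  gene); whether per-fold or pooled correlations should feed the FDR is
  genuinely open, and pooled is this package's choice (better-powered, one
  test per gene).
* Gene identifiers are harmonized across datasets by version-stripped
  intersection — also an open choice, made here because it is deterministic
  and loses nothing when annotations match.
* The CLI applies normalization stages in the order the user requests and
  records the applied order in the output header, since the correct order of
  quantile normalization relative to batch adjustment is context-dependent.

## Known limitations

The per-gene linear model cannot exceed the $\sqrt f$ ceiling of shared
variance, and in practice sits below it by the accuracy of factor recovery;
genes whose tissue expression is driven by tissue-private regulation are
invisible to this method by construction. Differential-expression testing
uses plain per-gene OLS with no variance moderation, which is conservative
and noisy at small $n$ relative to empirical-Bayes approaches (the log2 fold
changes that feed concordance are unaffected by moderation). The
`reference_significant` concordance filter gates genes on the *reference*
table's FDR; an `all_shared` mode is provided because the choice of which
side's FDR should gate the gene set is not settled.
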