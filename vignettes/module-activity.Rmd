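---
title: "Module activity from the first principal component: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module activity from the first principal component}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roma)
```

## The model

Many questions in transcriptomics and proteomics reduce to: how active is a
*module* — a transcription factor's target set, a pathway, a co-expression
cluster — in each individual sample? The simplest linear model of regulation
posits that the expression of gene $g$ in sample $s$ is driven by one hidden
factor,

$$ X_{gs} \approx \alpha_g \, A_s + B_s , $$

where $\alpha_g$ is the gene's response coefficient, $A_s$ the factor's
activity in sample $s$, and $B_s$ a per-sample bias common to all genes.
Restricted to the genes of one module, the least-squares fit of this model is
exactly the first principal component (PC1) of the module submatrix: the
loadings are $\alpha$, and the per-sample PC1 scores are the **activity
estimates** $A_s$. The fraction of module variance explained by PC1, called
**L1**, measures *overdispersion*; the ratio **L1/L2** of the first to the
second explained fraction measures *coordination* — a large spectral gap
means one factor dominates. An overdispersed module need not be coordinated:
when two or more independent factors drive the same gene set, L1 is high but
L1/L2 stays near its random-set value. `run_roma()` quantifies both, with
empirical significance for each.

Gene rows are assumed centered (`center_rows()`, the default pipeline
setting); without it PC1 tends to capture differences in basal expression
level rather than coordinated variation. Double-centering would also remove
$B_s$, but it cannot hold for every gene subset simultaneously, so it is
optional (`centering = "double"`).

## The iterative SVD engine

`fit_pc1()` computes PC1 by alternating least squares, starting from a
seeded random activity vector:

1. $\alpha_g \leftarrow \sum_s X'_{gs} A_s \,/\, \sum_s A_s^2$, then
   re-center (standard mode) and normalize $\alpha$ to unit Euclidean norm;
2. $A_s \leftarrow \sum_g |w_g| \alpha_g X'_{gs} \,/\, \sum_g |w_g| \alpha_g^2$;

until the loading vector changes by less than `tol` (default $10^{-9}$,
`max_iter` 10000). Gene weights $|w_g|$ — supplied per module, magnitudes of
the signed GMT weights — enter the fitted objective
$\sum_g |w_g| \sum_s (X'_{gs} - \alpha_g A_s)^2$ through the activity update
and the variance fractions; $\alpha$ is normalized in the *unweighted* norm,
following the printed constraint $\sum_g \alpha_g^2 = 1$. A uniform
rescaling of all weights therefore leaves the fit unchanged.

Two centering modes define the residual matrix $X'$:

* **standard**: $B_s$ is the weighted per-sample mean over module genes, and
  the loadings satisfy the zero-sum constraint $\sum_g \alpha_g = 0$ (for
  uniform weights);
* **fixed center** (the default): $X' = X - C$ with $C$ the per-sample mean
  over *all* dataset genes (`global_center()`). PC1 is forced through the
  center of the global distribution, so a gene set *shifted* away from the
  bulk of the data — all targets up-regulated together, say — scores high
  activity even if it is not internally overdispersed. No zero-sum
  constraint applies, and all loadings may share a sign.

One design point deserves a note. In standard mode with non-uniform weights,
the engine re-centers $\alpha$ with its *weight-weighted* mean rather than
the plain mean. Because the residual columns have weighted mean zero by
construction, this projection is a no-op at the fixed point — it only
suppresses drift along the constant direction during iteration — and it
keeps the converged solution identical to the top eigenvector of the
weighted covariance. With uniform weights it reduces to the plain zero-sum
constraint. Re-centering with the unweighted mean instead would bias the
weighted fit away from the eigensolver solution, which the test suite checks
against to $10^{-8}$.

L1 is computed from the weighted residual norm,
$L_1 = 1 - \|X' - \alpha A^\top\|^2_w / \|X'\|^2_w$. The second component is
fitted by the same iteration on the deflated matrix $X' - \alpha A^\top$ and
L2 is its incremental explained fraction of the *original* variance; this
matches standard SVD deflation and the dense eigendecomposition used as an
independent oracle in the tests. Degenerate submatrices with zero weighted
variance are rejected with an error; non-convergence returns the best
iterate with a warning.

## Orientation

PC1 is defined up to sign. When module genes carry signed weights
(activators positive, inhibitors negative), `orient_pc1()` picks the
orientation with $\sum_{g \in W} w_g \alpha_g > 0$ over the signed subset
$W$. Without signed genes (or at an exact zero sum) the fallback orients the
activity to correlate non-negatively with the per-sample mean of the module
submatrix; an exactly zero correlation leaves the fit as computed and logs
the fact. Orientation negates loadings and activity of component 1 only —
the PC2 projections reported in the per-module gene tables are unaffected.

## Robust PC1

A single aberrant gene can capture PC1 outright. `robust_filter()` applies
leave-one-out: for each gene $i$ it recomputes L1 with that gene removed,
converts the resulting $L_1^i$ distribution to z-scores (sample standard
deviation), and removes all genes with $|z| > z_{\max}$ (default 3.0) in a
single pass — the filter is not iterated, and z-scores are not re-estimated
after removals. "Points" here are genes (rows), the entities a module
defines. Edge cases: fewer than 3 genes skips filtering; a zero-spread
distribution removes nothing; if removal would leave fewer than 2 genes
(the minimum a rank-1 fit needs), nothing is removed and a warning is
issued. Final scoring always re-fits on the retained genes.

## Significance

Random gene sets also have a PC1, and the L1 expected for one depends
strongly on set size — small random sets explain a much larger fraction of
their variance. `run_roma()` therefore builds empirical null distributions
from `K` random gene sets (uniform draws from all dataset genes, unit
weights, no outlier filtering — a random set carries no prior structure; the
same mode and center as real modules, since the statistic must be
comparable). Building one null per distinct module size is wasteful, so
nulls are sampled only on a grid of sizes uniform in log scale between the
smallest and largest *retained* (post-match, post-outlier) module size
(`build_size_grid()`, default 10 points), and each module is compared
against the grid size nearest in log scale, ties toward the smaller size.

Empirical p-values use the add-one permutation convention,
$p = (1 + \#\{\text{null} \ge \text{observed}\}) / (K + 1)$, so $p = 0$ is
impossible and the attainable minimum is $1/(K+1)$ — 0.001 at the default
`K = 999`. Raw empirical p-values are the primary output; Benjamini-Hochberg
adjusted columns (`p_L1_BH`, `p_L1_div_L2_BH`) are appended to the score
table as a clearly labeled extra. Null sampling derives one seed per grid
size from the master `null_seed`, so enlarging the grid never changes
existing nulls.

## Preprocessing and missing values

Input is a tab-delimited genes-by-samples matrix (unique gene names; header
with or without a corner label) and a GMT file in which a token `GENE[w]`
attaches a signed weight — plain tokens keep weight $+1$ with undefined
sign, so the files remain loadable by ordinary GMT parsers. Gene matching
between GMT and expression rows is exact and case-sensitive.

Missing entries are imputed before scoring by a low-rank approximation
(`impute_missing()`): the model $X_{gs} \approx B_s + \sum_{k=1}^{k_{rank}}
\alpha_{gk} A_{sk}$ is fitted by the same alternating updates as the PC1
engine with every sum restricted to observed entries, and missing cells are
filled from the reconstruction. Observed entries are never altered. The user
chooses `k_rank`; convergence is declared when the relative Frobenius change
of the reconstruction drops below $10^{-8}$ (default), with a cap of 1000
sweeps. The global center is computed after imputation, on the completed
matrix, before module extraction.

## The synthetic-data generator

`simulate_expression()` instantiates the generative model the method
inverts: planted gene $g$ is $\sum_k \alpha_g^{(k)} A_s^{(k)} +
\mathcal{N}(0, \sigma^2)$ around iid Gaussian background genes, with rows
subsequently row-centered. Signal strength is reported as per-gene
signal-to-noise ratio: with unit-norm loadings over $n$ genes, activity
standard deviation $\mathrm{sd}(A) = \mathrm{SNR} \cdot \sigma \sqrt{n}$
gives each gene signal sd equal to $\mathrm{SNR} \cdot \sigma$. A
`planted_module_spec` carries the first factor's loadings and activity
explicitly; for `n_factors > 1` the extra factors get random unit loadings
and centered activities rescaled to *exactly* the first factor's standard
deviation — equally strong independent factors, which is what makes the
multi-factor case overdispersed but not coordinated. Half of each default
planted module's loadings are negative and the emitted GMT weights carry
those signs, so orientation is exercised end to end. Gaussian noise is a
deliberate simplification: the generator does not emulate count
distributions, dropout, library-size variation or gene-gene background
correlation, so passing recovery tests demonstrate correctness of the
estimator under its own model, not robustness to every artefact of real
single-cell data.

## Numerical and scale choices

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path in seconds: oracle comparisons on
200 random matrices up to 50 genes x 30 samples; activity recovery on 50
genes x 20 samples at per-gene SNR 2 over 20 replicates with `K = 199`;
null calibration on a 2000 x 30 pure-noise matrix with 200 test modules and
`K = 200`; a 21-gene fixture with one 100x-amplitude gene for the outlier
filter; an exact rank-2 matrix with 10% masked entries for imputation. All
randomness is seeded; two runs with the same configuration produce
byte-identical output tables.

Known limitations: the uni-factor model ignores inter-module crosstalk; L1
significance is assessed against size-matched random sets, not against
gene-identity-preserving permutations, so co-expression structure shared by
many genes inflates nulls and observed scores alike; the log-scale grid
approximates size dependence (module sizes far from any grid point borrow a
slightly mis-sized null); and the two-group comparison uses the asymptotic
Kolmogorov-Smirnov p-value, which is approximate for small sample counts.
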