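---
title: "Kernel PLS gene selection: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel PLS gene selection: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpls)
```

## The problem

Expression studies routinely classify a few dozen samples described by
thousands of genes. Filter-style gene selection — rank genes before any
classifier sees them — is the cheapest and least overfitting-prone option,
but univariate filters ignore gene–gene dependence, and the common
multivariate filters model that dependence only linearly. `kpls` ranks
genes with partial least squares run in a reproducing-kernel Hilbert
space: sample similarity is measured by a kernel, so nonlinear structure
among genes can contribute to the components, while every expensive
operation involves only the $n \times n$ Gram matrix and is therefore
insensitive to the gene count.

## Model and algorithm

Let $X$ be the $n \times p$ expression matrix and $Y$ the $n \times c$
one-hot class indicator with centered columns (`encode_labels()`). The
Gram matrix $K_{ij} = k(x_i, x_j)$ is double-centered,
$K \leftarrow (I - \tfrac1n \mathbf{1}\mathbf{1}')\,K\,(I - \tfrac1n
\mathbf{1}\mathbf{1}')$, the feature-space analogue of column-centering
$X$. Centering is applied always: the algorithm assumes zero-mean
variables, and with the linear kernel this choice makes the kernel scores
coincide exactly with classical NIPALS PLS2 on the centered data — a
correspondence the test suite verifies against an independently coded
primal oracle.

Each component is found by the alternating iteration

$$t \leftarrow \frac{K u}{\lVert K u \rVert}, \qquad
  c \leftarrow Y' t, \qquad
  u \leftarrow \frac{Y c}{\lVert Y c \rVert},$$

whose fixed point makes $t$ the dominant eigenvector of $K Y Y'$. Both $t$
and $u$ are renormalized every pass (the standard kernel-NIPALS
convention; it leaves the fixed point of $t$ unchanged). Convergence is
measured on the change in $t$, with tolerance `inner_tol = 1e-10` and a
cap of 500 iterations; for $c = 2$ the indicator has rank one and the loop
closes in a single pass. Two deterministic conventions remove the
remaining ambiguity: the starting $u$ is the first indicator column with
nonzero norm, and the sign of $t$ is flipped so that the largest-magnitude
entry of $Y't$ is positive. The whole fit is consequently bit-reproducible;
no randomness is involved anywhere in the fitting path.

After extraction, $Y \leftarrow Y - t t' Y$ and
$K \leftarrow (I - tt') K (I - tt')$. These projections guarantee
$t'Y_{\text{next}} = 0$ and $K_{\text{next}}t = 0$, hence pairwise
orthogonal score vectors and a non-increasing response residual norm —
both asserted as invariants in the tests. Two classes are always encoded
as the full two-column (rank-one) centered indicator rather than a single
±1 column, keeping one code path for every class count.

## How many components: the kernel Fisher criterion

Each component's scores get a Fisher discriminant ratio
$J_h = \sum_i n_i (m_i - m)^2 \big/ \sum_i \sum_{j \in i} (t_j - m_i)^2$.
A large $J_h$ means the component separates the classes. The number of
components is decided self-adaptively: component 1 is always kept, and
component $h$ is kept while $J_h \ge \lambda_{\mathrm{rel}} \cdot J^*$
with $J^*$ the largest *finite* ratio seen so far. The threshold is
relative because Fisher ratios are scale-dependent across datasets; a
fixed absolute cut would have to be re-tuned per study. Defaults:
$\lambda_{\mathrm{rel}} = 0.05$, a hard cap of `max_components = 10`
(further capped at $n - 1$), and a floor of one component. Infinite
ratios (perfect separation, zero within-class scatter) count as "largest
seen" and never trigger stopping. Extraction also halts if the response
residual is numerically exhausted (`y_exhausted`), which additionally
covers the rare case of the kernel matrix running out of rank. Passing
`n_components` bypasses the rule when a fixed count is wanted, e.g. for
oracle comparisons.

In practice the rule is strongly conservative in the $p \gg n$ regime:
with ~1000 genes the centered Gram matrix concentrates, the first score
vector is already close to the class indicator, $J_1$ is large, and later
components rarely clear 5% of it. On permuted-label null data the median
retained count is 1 (the acceptance script recomputes this), so the rule
does not hallucinate structure.

## From components to genes

Component $h$ maps back to genes through the loading
$w_h = X' t_h / \lVert X' t_h \rVert$ ($X$ column-centered). Gene $j$'s
raw score is the accumulated variation explanation
$\sum_h \mathrm{Rd}_h\, w_{hj}^2$, where
$\mathrm{Rd}_h = \frac1c \sum_m \mathrm{cor}^2(Y_{\cdot m}, t_h)$ weights
each component by how much of the class indicator it explains; the
multi-class weighting is uniform over the $c$ columns. Scores are
normalized to sum to one — a rank-invariant convention that makes
importances comparable across runs — and ties are broken by ascending
gene id so rankings are deterministic. No $\sqrt{p}$-style VIP scaling is
applied; it would cancel in the normalization anyway. Genes are centered
but deliberately not standardized to unit variance before scoring
(`loading = "corr"` provides the correlation-based alternative when gene
scale should not influence the ranking).

The default selection size is $k = 30$: across selection sizes,
classification performance typically improves steeply up to ~25 genes and
plateaus in the 20–50 range, so the midpoint is a sensible default and
`select_top_k()` takes any $k$.

## The synthetic generator

`simulate_microarray()` produces the study conditions used throughout the
tests: $n = 60$ samples, $p = 1000$ genes, balanced classes, 5
linear-informative genes (class-mean ladder with shift
$1.5 \cdot \sigma$), 5 nonlinear-informative genes, 40 redundant genes
(correlation 0.8 copies of random informative parents) and 950 noise
genes of SD 1. The nonlinear genes are built to be invisible to any
per-gene mean comparison: for two classes they come in XOR pairs — each
gene is a symmetric $\pm a$ two-state signal (measured with noise
$0.25\sigma$, as for a tight bimodal expression switch), and the class
determines only whether the pair's signs agree — plus a variance-coded
leftover when the count is odd; for three or more classes each gene
places samples at a class-specific distance from zero with random sign.
The per-gene class means are identical by construction, which the test
suite verifies by one-way ANOVA across seeds.

Parameters were chosen once as plausible microarray-like values (effect
size 1.5 SD is a clearly-but-not-trivially separable shift at $n = 60$;
redundancy 0.8 mimics co-expressed probe sets). What the generator does
*not* emulate: probe-level noise models, batch effects, heavy-tailed
intensities, missingness, or correlated noise blocks — so green tests on
this generator demonstrate algorithmic correctness and the intended
selection behaviour, not performance on any particular real dataset.

## What the importance score can and cannot recover

An honest limitation, measured rather than assumed. The importance score
weights gene $j$ on component $h$ by $w_{hj} = (X't_h)_j$, a covariance.
Retained components are, by design, strongly correlated with the class.
For a gene constructed to have *zero class-mean difference* (the XOR and
variance-coded genes above), the covariance with any function of the
class alone is zero in expectation, so its loading on class-aligned
components is pure $O(1/\sqrt n)$ sampling noise — statistically
indistinguishable from the 950 noise genes. Components that do load
heavily on the XOR genes exist and are extracted when more components are
forced (their within-class latent state is a high-variance kernel
direction), but their $\mathrm{Rd}$ is three orders of magnitude below
the first component's, so the $\mathrm{Rd}$-weighted sum cannot promote
them. Under the default conditions the RBF ranking recovers on average
about 5.5 of the 10 planted informative genes in the top 30 (essentially
the 5 linear ones plus redundant copies), and its recall of the
marginally-null nonlinear genes matches — does not exceed — that of the
linear filter. The corresponding acceptance test is therefore expected to
fail and is kept failing rather than weakened: kernelizing the component
extraction does not, by itself, make a covariance-based gene score
sensitive to marginally-null genes. Nonlinear kernels still help when
genes carry *some* marginal signal that combines nonlinearly, and the
kernel components themselves separate nonlinear class structure well —
it is the back-projection to individual genes that is intrinsically
linear.

## Evaluation harness

`evaluate_selection()` follows the usual protocol for these sample sizes:
stratified 10-fold cross-validation for two-class problems and 5-fold for
multi-class (some classes are too small for 10 folds), with fold dealing
done per class round-robin after a seeded shuffle so fold class
proportions never deviate by more than one sample. Gene selection is
re-fitted inside every training fold; the held-out rows cannot influence
the selected panel, a property asserted directly in the tests. Metrics:
accuracy, the Mann–Whitney formulation of the two-class AUC (ties count
one half; multi-class AUC is deliberately not defined here — kappa covers
that case), and Cohen's kappa from the fold confusion matrix. Classifiers
are consumed through a train/predict contract; built-ins are
5-nearest-neighbour (`class::knn`) and an RBF-kernel SVM with library
defaults (`e1071::svm`) — no hyperparameter search is performed, which is
a documented simplification relative to swarm-optimized SVM tuning.

## Numerical choices and degenerate inputs

* Default RBF/polynomial `gamma` is $1/(p \cdot \mathrm{var}(X))$
  (overall element variance): scale-free and robust to gene count.
* Missing values are rejected at every entry point with a pointer to
  impute upstream; silent imputation is out of scope.
* A zero-variance score vector yields $\mathrm{Rd} = 0$ with a warning; a
  zero loading column contributes nothing (logged); all-zero
  $\mathrm{Rd}$ aborts with "no component explains the response".
* Gram symmetry is enforced by averaging with the transpose; squared
  distances are floored at 0 before `exp()`.
* The inner loop is a power iteration; near-degenerate eigengaps converge
  slowly, so oracle-comparison code raises `inner_max_iter` rather than
  loosening tolerances.

## Problem sizes used in the shipped checks

Unit and acceptance tests run at $n \le 72$, $p \le 7129$, 20 seeds for
the simulation-based properties — sizes chosen so the whole suite
completes in seconds on one core while still exercising the $p \gg n$
regime; the $72 \times 7129$ case matches a classic leukemia cohort's
shape and ranks in well under a second because all per-component work is
$O(n^2)$.
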