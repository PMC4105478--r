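# kpls — kernel partial least squares gene selection

`kpls` is an R package for multivariate, classifier-independent gene
selection in high-dimensional expression data (bulk microarray or
pseudo-bulk single-cell matrices), where the number of genes *p* vastly
exceeds the number of samples *n*. Univariate filters score genes one at a
time and miss genes whose relevance only shows through interactions;
classical PLS-based filters capture multivariate structure but only linear
combinations. `kpls` works in a reproducing-kernel Hilbert space, so gene
interactions that are nonlinear in the original space become accessible,
while all heavy computation stays on the *n* × *n* Gram matrix.

## The method

Given an expression matrix **X** (*n* samples × *p* genes) and class labels
encoded as a column-centered one-hot indicator **Y** (*n* × *c*):

1. **Gram matrix.** K<sub>ij</sub> = k(x<sub>i</sub>, x<sub>j</sub>) for a
   linear, RBF or polynomial kernel, then double-centered in feature space:
   K ← (I − **11**′/n) K (I − **11**′/n).
2. **Component extraction (kernel NIPALS).** Iterate
   t ← K u / ‖K u‖, c ← Y′t, u ← Y c / ‖Y c‖ until t stabilises. The fixed
   point is the dominant eigenvector of K Y Y′; for two classes the loop
   closes in one pass. After each component both working matrices are
   deflated: Y ← Y − t t′Y, K ← (I − t t′) K (I − t t′), which makes the
   score vectors t₁, t₂, … mutually orthogonal.
3. **Self-adaptive component count.** Each component gets a kernel Fisher
   discriminant ratio J<sub>h</sub> = Σᵢ nᵢ(mᵢ − m)² / Σᵢ Σ<sub>j∈i</sub>
   (t<sub>j</sub> − mᵢ)² over its scores. Component h is retained while
   J<sub>h</sub> ≥ λ · J*, with J* the largest finite ratio seen so far
   (λ = 0.05 by default), so the component count adapts to the dataset
   instead of being fixed by hand.
4. **Gene importance.** Component h is mapped back to genes by the
   unit-norm loading w<sub>h</sub> = X′t<sub>h</sub>, and gene j is scored
   by its accumulated variation explanation
   score<sub>j</sub> = Σ<sub>h</sub> Rd<sub>h</sub> · w²<sub>hj</sub>,
   where Rd<sub>h</sub> is the mean squared correlation between
   t<sub>h</sub> and the columns of **Y**. Scores are normalized to sum to
   one and genes ranked; the top k (default 30) form the selected panel.

The package also ships a synthetic microarray generator with known
ground-truth gene roles (linear-informative, nonlinear-informative,
redundant, noise), and a stratified cross-validation harness that
re-selects genes inside every training fold (no selection leakage) and
reports accuracy, AUC (two-class) and Cohen's kappa.

## Worked example

```r
library(kpls)

sim <- simulate_microarray(n_samples = 60, n_genes = 1000, seed = 42)
fit <- kpls(sim$expression, sim$labels, kernel = "rbf")
fit
#> Kernel PLS feature-selection fit
#>   samples: 60  genes: 1000  classes: 2
#>   kernel: rbf (gamma = 0.0009827)
#>   components retained: 1  (stopping: threshold )
#>   per-component Rd: 0.993
#>   per-component J:  148

rk <- kpls_rank(sim$expression, sim$labels, kernel = "rbf")
head(rk, 5)
#>    gene_id importance rank
#> 1 gene0003 0.03040523    1
#> 2 gene0004 0.02781739    2
#> 3 gene0005 0.02715237    3
#> 4 gene0001 0.01844823    4
#> 5 gene0032 0.01746554    5

ev <- evaluate_selection(sim$expression, sim$labels, top_k = 30,
                         classifier = "knn", seed = 1, kernel = "rbf")
ev
#> Cross-validated gene-selection evaluation (10-fold, top 30 genes, knn)
#>  metric      mean         sd
#>     acc 0.9666667 0.07027284
#>     auc 0.9888889 0.03513642
#>   kappa 0.9333333 0.14054567
```

One component is retained: its scores explain 99% of the indicator
variance (Rd = 0.993) and separate the classes with Fisher ratio 148,
while the second candidate falls below 5% of that and stops extraction.
The top-ranked genes are dominated by the planted class-shifted genes
(`gene0001`–`gene0005`) and their correlated redundant copies
(e.g. `gene0032`), and a 5-nearest-neighbour classifier on the selected
30-gene panel reaches 96.7% cross-validated accuracy.

The same pipeline is available from a shell:

```sh
Rscript inst/cli/kpls.R simulate --out data/ --seed 7
Rscript inst/cli/kpls.R rank --expr data/expression.tsv --labels data/labels.tsv \
        --kernel rbf --top-k 30 --out ranking.tsv
Rscript inst/cli/kpls.R evaluate --expr data/expression.tsv --labels data/labels.tsv \
        --classifier knn --top-k 30 --report report.tsv
```

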