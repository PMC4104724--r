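---
title: "PLS-VIP differential expression: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PLS-VIP differential expression: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsvip)
```

## The model

`plsvip` detects genes whose expression differs between two groups (coded
0 = control, 1 = case) in a probes × samples log2 expression matrix. The
underlying model is a linear predictor of the binary phenotype from all
probes at once,

$$ y = \sum_{i=1}^{p} \alpha_i x_i + b, $$

fitted not by least squares (impossible when $p \gg n$) but by partial
least squares: latent variables $t_k = X w_k$ are extracted so that the
covariance between the predictor scores $t_k$ and the response scores
$u_k$ is maximal, with deflation between components. We use the NIPALS
iteration for a single response: starting from $u_0 = y$, iterate

1. $w = X^\top u_0$, $w \leftarrow w / \lVert w \rVert$
2. $t = X w$
3. $c = y^\top t$, $c \leftarrow c / \lvert c \rvert$
4. $u = y c$

until $\lVert u - u_0 \rVert < 10^{-8}$, then deflate
$X \leftarrow X - t (t^\top X)/(t^\top t)$ and
$y \leftarrow y - t (t^\top y)/(t^\top t)$ and repeat for the next
component. For a single response the loop converges in one pass, because
$y^\top X X^\top y \ge 0$ makes the first sign choice stable; the fitter
still carries a tolerance and an iteration cap so that numerically
degenerate inputs fail loudly rather than silently. Deflation in the raw
"$X - tt^\top X$" form is dimensionally consistent only for unit-norm
scores, so the standard normalized form above is used; the two coincide
when $\lVert t \rVert = 1$.

Probe importance is summarized by the variable importance in projection,

$$ \mathrm{VIP}_j \;=\; \sqrt{\; p \cdot
   \frac{\sum_{k=1}^{h} \mathrm{Cor}^2(y, t_k)\, w_{kj}^2}
        {\sum_{k=1}^{h} \mathrm{Cor}^2(y, t_k)} }, $$

with unit-norm $w_k$ and Pearson correlation. Since
$\sum_j w_{kj}^2 = 1$, the identity $\sum_j \mathrm{VIP}_j^2 = p$ holds
for every fitted model; the test suite asserts it after every fit,
including inside permutation replicates.

## Choices the printed algorithm leaves open

* **Centering and scaling.** Probe columns are mean-centered and scaled
  to unit variance by default (`scale_columns = TRUE`), and the response
  is mean-centered. Without scaling, high-variance probes dominate
  $w = X^\top u$ irrespective of their association with the phenotype.
  Scaling is a switch, not a constant, because unscaled analyses are
  defensible when variance itself carries signal.
* **Initialization.** $u_0 = y$ deterministically. A random start adds
  nothing for a univariate response (the iteration converges in one
  pass from any start in the $y$ direction) and would break
  reproducibility.
* **Sign convention.** Each $w_k$ is flipped so its largest-magnitude
  entry is positive. VIP is sign-invariant, so this only pins down the
  orientation of scores across platforms and BLAS builds.
* **Classifier rule.** Cross-validated "prediction accuracy" needs a
  classification rule; with a 0/1-coded response the fitted score is
  thresholded at 0.5.
* **Zero-variance probes** are dropped (with a message) before fitting:
  they cannot be scaled and carry no between-group information.

## Selecting the number of latent variables

`choose_h_cv()` runs stratified 3-fold cross-validation (folds are drawn
within each class, in sample-ID-sorted order so that reordering samples
does not change fold membership), fits one model with `h_max` components
per training split, and evaluates each candidate $h$ by truncating that
model. The chosen $h$ is the smallest one attaining the maximum mean
accuracy — the parsimony tie-break matters because accuracy curves
plateau once the signal is captured. On strongly separable synthetic
cohorts the curve reaches 100% accuracy within six components, the
behavior expected of a real case/control expression study with strong
signal.

## Permutation FDR

Significance is assigned by refitting the whole model (same $h$, same
standardization policy) on label permutations and pooling the null VIPs
over all probes and permutations:

$$ \mathrm{FDR}_i \;=\; \frac{1}{p}\left[
   \frac{\sum_{j=1}^{N} \sum_{i'=1}^{p}
   \mathbf{1}\!\left(\mathrm{VIP}_{i',j} > \mathrm{VIP}_i\right)}{N}
   \right], $$

with strict inequality (ties are not exceedances) and probes selected at
$\mathrm{FDR} < 0.01$ (strict). The inner sum runs over all probes
within each permutation — the only reading that yields a probe-specific
quantity. This pooled form is *not* the conventional
"null exceedances / observed discoveries" permutation FDR; that
estimator is available via `estimator = "tail_ratio"` for comparison but
is never the default, because the pooled form is the method this package
implements. The default number of permutations is 10000; tests and the
bundled examples use 100–200, which is enough for the 0.01 threshold to
be meaningful at a few thousand probes ($N \cdot p$ null values).

Permutations are drawn in sample-ID-sorted space, so identically
reordering the expression columns and phenotype leaves both VIP and FDR
bit-identical — a cheap but effective guard against label-alignment
bugs. The CV-chosen $h$ from the observed labels is held fixed across
permutations; re-running CV inside each permutation would change the
meaning of the null distribution.

Under a fully null cohort the pooled estimator behaves like an
exchangeable rank statistic: the expected fraction of probes with
$\mathrm{FDR}_i < q$ is $q$ itself, not less. Users should therefore
read it as a calibrated selection score rather than a conservative
error bound; at the default threshold this distinction is the difference
between "about 1% of null probes selected" and "at most 1%".

## Enrichment and network stages

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ via `phyper`, with the universe defined per namespace as
the annotated genes appearing in at least one set of that namespace —
mirroring how pathway-mapped and GO-annotated gene counts are reported
separately in expression studies. Sets with zero overlap are suppressed
(their over-representation is untestable), and Benjamini–Hochberg
q-values are computed within each namespace; both p and q are emitted
so thresholding stays with the caller.

The interaction stage induces the subgraph of the background
protein–protein interaction network on the selected genes (selected
genes absent from the background are dropped; isolated selected genes
stay as degree-0 nodes), counts distinct neighbors as degree, and calls
hubs at degree ≥ 10. The boundary is inclusive: a published hub list
whose smallest member has degree exactly 10 forces "degrees over 10" to
be read as ≥, and both the cutoff and its strictness are exposed.
Self-loops never contribute to degree. Degrees are computed on the
induced subnetwork, not the full background graph, matching the
construction of a DE-gene-only interaction figure. Note that induced
degrees can be far below background degrees: restricting a sparse
Erdős–Rényi background (mean degree 2) to ~100 selected genes leaves
almost no edges, so synthetic hub calls are only expected on the
background graph — real interaction databases, whose degree
distributions are heavy-tailed, are what make degree-10 hubs plausible
inside a DE subnetwork.

## The synthetic-data generator

`generate_expression()` emulates a 63-case / 20-control peripheral-blood
microarray cohort: per-probe baselines uniform on [4, 12] (the usual
RMA log2 range), i.i.d. Gaussian noise on the log2 scale, and a planted
mean shift of `effect_size` log2 units in cases for `n_de` probes, half
up- and half down-regulated by default (`direction_bias` reproduces
asymmetric splits). The defaults — 2000 probes, 100 DE probes at 1.5
log2 units over unit noise — give a realistic moderate-signal regime:
per-probe two-sample $t \approx 6$, so single-probe testing would also
find most of them, but the matrix is small enough that the whole
pipeline (including 200 permutation refits) runs in seconds.

`generate_annotation()` maps probes many-to-one onto symbols (1.2
probes/gene by default) to exercise the rule that a gene is called
differentially expressed when *any* of its probes is selected.
`generate_gene_sets()` plants enrichment by drawing a fraction
`enrichment_strength` of a set's members from DE-mapped genes;
`generate_interactions()` plants hubs by topping up chosen nodes over an
Erdős–Rényi background until they reach a target degree.

What the generator does **not** model: array-specific technical
artifacts, batch effects, probe-level normalization, correlated gene
modules, or heavy-tailed noise. Passing tests therefore demonstrate
algorithmic correctness and calibration under the stated generative
model, not robustness to the full messiness of real microarray data.

## Numerical notes and limitations

* Convergence is declared at $\lVert u - u_0 \rVert < 10^{-8}$
  (configurable); rank exhaustion raises an error naming the achievable
  number of components rather than returning silently truncated models.
* Exceedance counting pools $N \cdot p$ doubles and counts strict
  exceedances by binary search on the sorted pool, so counts are exact
  (no floating accumulation error) and memory stays at a few MB for
  $N = 200$, $p = 2000$. At the published $N = 10000$ and $p \sim 5 \cdot 10^4$
  the pool is ~4 GB; runs of that size should reduce `n_perm` or process
  permutations in blocks.
* Test and example problem sizes (hundreds to a few thousand probes,
  100–200 permutations, 10–20 seeds) were chosen so the full suite
  completes in a few minutes while keeping every planted-signal check
  well-powered.
* The pooled FDR's at-the-boundary calibration (see above) means
  selection counts on pure-noise data hover around, not strictly below,
  the nominal threshold fraction.
* The package deliberately implements single-response PLS only; no
  kernel, sparse or orthogonalized variants, no gene-level VIP
  aggregation, and no topology-aware enrichment.
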