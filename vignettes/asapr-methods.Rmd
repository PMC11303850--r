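---
title: "Methods: pseudobulk topic modelling of single-cell counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudobulk topic modelling of single-cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the design choices made where
the design was genuinely open.

## The model

Single-cell counts form a sparse non-negative matrix $X \in
\mathbb{R}_{\ge 0}^{D \times n}$ (genes by cells). The generative view is a
Gamma–Poisson (Poisson matrix factorization) topic model:

$$\beta_{ik} \sim \mathrm{Gamma}(a_0, b_0), \quad
  \theta_{jk} \sim \mathrm{Gamma}(a_0, b_0), \quad
  X_{ij} \sim \mathrm{Poisson}\Big(\sum_{k=1}^{K} \beta_{ik}\theta_{jk}\Big).$$

$\beta$ is a gene-by-topic dictionary, $\theta$ the per-sample topic
loadings. The per-topic scale is not identifiable; `to_multinomial_scale()`
absorbs each dictionary column total into the loadings and normalizes, so
dictionary columns become topic-specific gene frequencies and loading rows
probability vectors.

Fitting this model on hundreds of thousands of cells is expensive, so the
package first collapses cells into at most $2^d$ *pseudobulk* samples and
fits the factorization there, then recovers per-cell loadings by a fast
fixed-dictionary regression.

## Step 1: random-projection pseudobulk

Cells are projected onto $d$ i.i.d. Gaussian directions, $Q = RX$, computed
in column chunks over the sparse matrix (memory is $O(dn)$ plus one pass
over nonzeros). Random projections approximately preserve pairwise
distances, so transcriptionally similar cells receive similar projections.
The rows of $Q$ are then decorrelated by an economical SVD $Q = USV^\top$;
we keep the orthonormal rows of $V^\top$ — dropping $S$ changes nothing
once rows are standardized — and standardize each row to mean zero, unit
population standard deviation. Each cell's $d$ signs form a binary code,
read as an integer leaf index in $[0, 2^d - 1]$; a coordinate exactly zero
branches to 0 (the inequality is strict). Cells in a leaf are summed and
each pseudobulk column is rescaled to $10^4$ total counts.

Numerical decisions:

* **SVD sign convention.** Singular vectors are sign-ambiguous; each row's
  largest-magnitude entry is forced positive, making results reproducible
  across platforms.
* **Rank deficiency.** Singular values below `max(sv) * max(d, n) * eps`
  are treated as zero; the corresponding rows are zeroed (all cells branch
  left at that level) with a warning, as are zero-variance rows that would
  otherwise divide by zero during standardization.
* **Counts are projected raw.** No log transform or per-cell normalization
  precedes projection (cells are only depth-normalized after aggregation);
  a `log1p` flag exists but is off by default.
* **Empty leaves are dropped**; leaf identities are kept as metadata.
* **Chunking is exact.** Projection and aggregation over cell blocks
  (default 10,000) give bit-identical results for any block size — a tested
  invariant, since dot products and integer sums do not depend on the
  partition.

`d` defaults to 10 in the pipeline wrapper (capacity 1,024); at least 6 is
needed before leaf occupancy aligns well with cell types on the synthetic
benchmark, with little gain beyond.

## Step 2: variational inference

The Poisson log-likelihood is non-conjugate with the Gamma priors, so a
mean-field bound introduces per-entry multinomial responsibilities
$z_{ijk}$ with $\sum_k z_{ijk} = 1$:

$$\log z_{ijk} \propto \mathbb{E}[\ln \beta_{ik}] +
  \mathbb{E}[\ln \theta_{jk}],$$

followed by conjugate updates

$$\theta_{jk} \mid \cdot \sim \mathrm{Gamma}\Big(a_0 + \sum_i Y_{ij} z_{ijk},\;
  b_0 + \sum_i \mathbb{E}[\beta_{ik}]\Big), \qquad
  \beta_{ik} \mid \cdot \sim \mathrm{Gamma}\Big(a_0 + \sum_j Y_{ij} z_{ijk},\;
  b_0 + \sum_j \mathbb{E}[\theta_{jk}]\Big).$$

Implementation notes:

* **Sparsity is exact, not approximate.** Entries with $Y_{ij} = 0$
  contribute nothing to the count-weighted sums, so responsibilities are
  computed only at stored nonzeros (an Rcpp kernel with softmax
  max-subtraction); the $D \times L \times K$ tensor is never materialized.
  A naive full-tensor implementation serves as a test oracle on small
  instances.
* **ELBO.** Using $\sum_k z_k(w_k - \log z_k) = \mathrm{logsumexp}(w)$, the
  data term reduces to $\sum_{ij} Y_{ij}\,\mathrm{logsumexp}_k(w_{ijk})$;
  the Poisson rate term and the Gamma prior/entropy terms are added in
  closed form. The additive constant $-\sum_{ij}\log Y_{ij}!$ is dropped
  consistently. The bound is evaluated at the top of each iteration (after
  the responsibility step, before the updates), which makes the recorded
  trace provably non-decreasing under coordinate ascent; the suite checks
  this at relative tolerance $10^{-8}$.
* **Hyperparameters.** $a_0 = b_0 = 1$ (a weakly informative
  Exponential(1) prior) — conventional defaults, exposed as options.
* **Initialization.** Dictionary shapes start at $a_0$ plus small seeded
  uniform noise; loading shapes start flat at $a_0$ (no per-sample noise),
  so inference is equivariant under sample permutation — permuting columns
  of $Y$ permutes the loading rows and leaves the dictionary unchanged, a
  tested property. Only the dictionary noise needs a seed.
* **Convergence.** Relative ELBO change below `tol` (default $10^{-6}$) or
  `max_iter` (default 500). On depth-normalized pseudobulk panels the ELBO
  magnitude is large, so a relative criterion can trigger early; the
  benchmark harness therefore caps iterations explicitly instead of
  relying on `tol` alone.

## Step 3: fixed-dictionary regression

Revisiting all cells with full per-gene responsibilities would not scale,
so each cell gets a single topic-responsibility vector:

$$\log \rho_{jk} = \frac{\sum_i Y_{ij}\,\mathbb{E}[\ln\beta_{ik}]}
  {\sum_i Y_{ij}} + \mathbb{E}[\ln\theta_{jk}], \qquad
  \theta_{jk} \mid \cdot \sim \mathrm{Gamma}\big(a_0 + \rho_{jk} c_j,\;
  b_0 + \textstyle\sum_i \mathbb{E}[\beta_{ik}]\big),$$

with $c_j$ the cell's total count. The division of the data term by $c_j$
is implemented exactly as written; an unscaled variant is available via
`scale_data_term = FALSE` without asserting which was intended. Cells start
from a flat $\mathbb{E}[\ln\theta]$ (the first $\rho$ is purely
dictionary-driven), alternate the two updates `n_iter = 10` times by
default, and are fully independent — chunking and ordering are bit-exact
invariants. Zero-count cells are dropped with a warning and listed.

**Sharpening dynamics.** Each alternation multiplies the topic odds by
approximately the data log-score gap (since
$\psi(a_0 + \rho c) - \log(\cdot)$ grows like $\log \rho$ for large $c$),
so repeated rounds drive $\rho$ toward the dominant topic. This behaves
like annealing for clustering — per-cell loadings become nearly discrete —
but de-calibrates mixture proportions: a 50/50 mixture of two topic
profiles regressed for many rounds drifts toward one vertex. Where
calibrated proportions matter (bulk projection for deconvolution), use few
rounds (1–2); the mixture-projection test runs at `n_iter = 2`. This is a
property of the collapsed per-cell bound, not of the full per-gene
inference, which an independently coded frozen-dictionary variant confirms
(normalized loadings correlate > 0.99 on small instances while not being
identical).

Bulk samples go through the same regression after intersecting gene
universes (absent genes are dropped with a message) and depth-normalizing
each column to $10^4$, matching the pseudobulk convention so the
dictionary's scale assumptions hold.

**Deconvolution** counts cell-type labels among the $k = 100$ (default)
nearest cells by Euclidean distance between normalized topic-proportion
vectors, with ties broken by cell index. It carries mixture information
only where per-cell loadings form overlapping continua around the bulk
point — closely related types, moderate sequencing depth. With extremely
separated types the per-cell loadings concentrate at simplex vertices and
the rule returns the majority label; this is a documented limitation of
neighbour counting, not of the estimator of $\theta$.

## The benchmark simulator

`make_benchmark()` emulates a sorted-reference copula scheme entirely in
code:

1. `make_reference()` builds per-type expression profiles: a shared
   log-normal baseline, a global per-type log-normal perturbation
   (`type_variation`, default sdlog 0.3 — sorted reference profiles differ
   transcriptome-wide, reproducing the high but imperfect between-type
   correlations of sorted immune profiles), and a disjoint marker block per
   type elevated `separation`-fold (default 5). Per-type means and a
   low-rank-plus-diagonal covariance are recorded on the log1p
   depth-normalized scale; a pool of `pool_size = 5` noisy profile
   replicates provides bootstrap marginals; pooled frequencies give the
   background null.
2. `sample_celltype()` draws a Gaussian vector per cell from the type's
   $(\mu_t, \Sigma_t)$, bootstraps an expression vector from the pool,
   sorts it, and assigns gene $g$ the order statistic at the ascending rank
   of its Gaussian coordinate — a Gaussian copula with bootstrap marginals.
   Gene–gene dependence comes from the Gaussian half; the pooled value
   distribution is preserved (checked by a two-sample KS statistic), while
   per-gene marginals are deliberately shifted by the mean structure.
3. `sample_null()` draws each background cell from
   $\mathrm{Multinomial}(\text{depth}, p)$ with the pooled frequencies.
4. `mix_and_depth()` depth-normalizes both halves, blends them as
   $\rho\,y^{(t)} + (1-\rho)\,\tilde y$, and integerizes with a single
   multinomial draw at the target depth — the convex mixture of normalized
   vectors is generally non-integer and the integerization step is
   otherwise unspecified, so one multinomial draw preserves count character
   and exact per-cell depth.

Within-type covariance defaults (`cov_rank = 3`, `cov_scale = 0.1`,
`cov_diag = 0.3`) keep the correlated share of within-type variation a
minority: a dominant low-rank component would make one labelled type appear
as several discrete sub-populations, contradicting the premise that one
type is one population. The `pool_size` knob plays the role of "how many
reference replicates" back the bootstrap marginals.

What the simulator does **not** emulate: batch effects, doublets, gene
dropout beyond multinomial sampling, per-gene dispersion families, or
zero-inflation classes. Passing benchmarks here shows the pipeline recovers
planted admixture structure under copula-correlated noise at controlled
depth — not that it is robust to artefacts real data may contain.

## Evaluation harness

Estimated partitions are compared to planted labels with the adjusted Rand
index (Hubert–Arabie, from the contingency table; identical trivial
partitions score 1), normalized mutual information (normalized by the
arithmetic mean of the entropies, $2I/(H_a + H_b)$; defined as 1 when both
partitions are trivial), and purity (majority overlap per cluster; its
degenerate maximum at all-singletons is a known caveat). All three are
label-permutation invariant and are cross-checked in the tests against
independent pair-counting and entropy implementations and against external
references.

`cluster_topics()` builds a 15-nearest-neighbour graph (Euclidean on
normalized proportions, ties by index) and partitions it with Leiden
community detection (igraph backend, modularity objective). A seeded
k-means fallback covers settings where a graph backend is unwanted. The
benchmark harness uses resolution 0.25, which on this simulator yields
cluster counts matching the planted number of types; higher resolutions
over-split saturated, very clean data and much lower ones under-merge at
moderate noise.

## Problem sizes used by the checks

The acceptance-style tests run at sizes chosen to exercise every claim
while keeping the suite quick: the accuracy sweep uses 13 types × 154
cells (~2,000), 1,000 genes, depth 10,000, tree depth 8, `K = 13`,
iteration cap 50, and 5 replicate seeds per $\rho \in \{0.01, 0.25, 0.5,
0.75, 1\}$; means across seeds are required to be non-decreasing in $\rho$
up to a pre-registered Monte Carlo slack of 0.02 (the standard error of a
5-replicate mean near saturation). The pseudobulk-vs-full comparison uses
the same data at $\rho = 0.5$. The deconvolution check uses two related
types (separation 1.5, `type_variation` 0.1, depth 500) and averages
recovered fractions over 5 replicate simulations in both mixture
orientations. Parameter recovery uses a 100 × 50, `K = 3` instance drawn
from the generative model.

## Known limitations

* Topic count `K` must be chosen by the user; no model selection is
  provided.
* The Step-3 sharpening dynamics make per-cell loadings nearly discrete
  after many rounds (see above).
* No batch correction, doublet handling or feature selection — the point
  of the pseudobulk construction is to avoid unvetted feature selection,
  and integration concerns are out of scope.
* Purity rewards over-partitioning; read it together with ARI/NMI.
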