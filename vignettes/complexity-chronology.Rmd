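---
title: "Methods: a complexity-constrained amino-acid chronology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a complexity-constrained amino-acid chronology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codechron)
```

## The model

The package treats each proteinogenic amino acid as a point in a metric
space whose coordinates are molecular complexity index values, and asks two
questions of the resulting geometry:

1. Does the minimum spanning tree (MST) of the point cloud, rooted at the
   least complex residue (glycine), order amino acids in a way consistent
   with proposed recruitment chronologies?
2. Are amino acids adjacent in that tree connected by more single-point
   codon interchanges than chance would give?

The underlying assumption is *incremental elaboration*: if molecular
complexity constrained recruitment, neighboring residues in complexity
space should be both chronologically and mutationally close. The MST is a
descriptive, parsimony-style summary of the cloud — it does not assert that
evolution performed a greedy optimization.

## Codon combinatorics

For amino acids $a_i, a_j$ with codon sets $C_i, C_j$ (standard code, RNA
alphabet, 61 sense codons), the connecting-mutation count is

$$S_{i \to j} = \sum_{c \in C_i}\sum_{c' \in C_j} \delta(c, c'),$$

with $\delta = 1$ iff the codons differ at exactly one nucleotide. The
capacity of $a_i$ is $M_i = 9 n_i$ ($3 n_i$ per position), where $n_i$ is
the codon degeneracy, and $F_{i \to j} = S_{i\to j}/M_i$. Substitutions
that create a stop codon are never counted in $S$ but remain in the
capacity denominator, which is defined purely from degeneracy. With these
conventions the per-pair background means over the 190 unordered pairs are
exactly $83/190$, $88/190$ and $25/190$ at positions 1–3 (0.44, 0.46, 0.13
at two decimals), and the expected per-position total of a randomly
labelled 20-node tree is $19 \times B(p)$: 8.300, 8.800, 2.500, and 19.600
overall.

Two definitional points deserve flagging. First, a *per-amino-acid average
of fractions* $\frac{1}{20}\sum_k S_k/(3 n_k)$ is a different quantity
(about 0.92 at position 1) and does not match the background values above;
the package implements the per-pair mean as normative and exposes the
other reading as `background_per_pair_mean(..., variant = "per_aa")` for
diagnostics only. Second, the per-pair mean multiplied by 19 is the exact
expectation of the permutation null for *any* fixed tree topology, because
under a uniform random labelling every edge is a uniform random unordered
pair — the null's closed form is topology-independent, which the
permutation engine's convergence tests exploit.

## Distances, embedding, neighborhood graph

Metrics are autoscaled column-wise (sample sd, $n-1$; a global scale factor
cancels in correlations, MST topology and ε expressed in sd units), and
distances are plain Euclidean norms in the full metric space. Min–max
normalization to $[0,1]$, when requested, is applied to the pooled
off-diagonal distances as a single population, not per row.

Classical MDS double-centers the squared distances and truncates the
eigendecomposition of the Gram matrix. Numerical choices:

* negative eigenvalues (non-Euclidean noise) are clipped to zero and
  reported in diagnostics, standard Torgerson practice;
* the embedding is canonicalized — eigenvalues descending, each axis
  sign-fixed so its largest-magnitude coordinate is positive — so repeated
  runs are bit-identical;
* reconstruction error is the mean and 95th percentile (linear
  interpolation between order statistics) of
  $|\hat d_{ij} - d_{ij}|/d_{ij}$ over pairs with $d_{ij} > 0$; the default
  dimension is the smallest with mean error below 2%.

The ε-neighborhood graph is the Vietoris–Rips 1-skeleton: an edge wherever
$d_{ij} \le \varepsilon_\text{total}$. The threshold is stated per
embedding dimension and scaled *linearly*,
$\varepsilon_\text{total} = \varepsilon \cdot \dim$ (so 1.0 sd per
dimension in a 7-D embedding means a total distance of 7); the √dim
alternative was rejected to match the stated equivalence of the reference
analysis. `min_connectivity_eps()` scans an ε grid upward literally (the
implementation does not shortcut through the MST), which lets the tests
assert the classical equivalence — connectivity is first achieved at the
largest MST edge weight — as a genuine cross-check between two routes.

The MST itself is computed by Prim's algorithm with edge weights taken from
the **original-space** distances, not the embedded ones. The two coincide
for topology wherever the embedding error is small, but original distances
are the cleaner definition; this was a genuinely open design point and is
the package default. Ties (impossible with real-valued complexity data,
possible in toys) break lexicographically by label pair, so the output is
deterministic.

## Chronology and ranks

The primary chronology score is cumulative root-to-node path weight from
glycine. The comparison variant is a rank composite: within each metric,
amino acids are ranked ascending with near-ties grouped — on the metric's
min–max-normalized scale, sorted neighbors within 0.005 share a rank — and
ranks are averaged across metrics. The 0.005 threshold is only meaningful
on a normalized scale, which is the package's stated convention (the raw
scales of the different indices differ by orders of magnitude).

## Enrichment statistics

Observed per-position counts are summed over the 19 tree edges and compared
with the permutation ensemble's $\mu \pm 1.96\sigma/\sqrt{N}$ (normal
approximation on the mean, exactly as the reference analysis defines its
CI; not a percentile bootstrap). `N = 1e5` by default; the engine is
vectorized (one index-lookup matrix per position) and seed-reproducible.
Because the denominators behind published per-tree "fraction of mutations"
columns are not reconstructible from their description, counts are the
normative statistic here; the reported fraction uses the convention
$\sum_\text{edges} S / \sum_\text{edges} M_i$ with $i$ the endpoint nearer
the root.

## Usage association

`ols_fit()` is unweighted ordinary least squares of usage on a chronology
score ($R^2$ = squared Pearson correlation; two-sided slope test on
$n - 2$ df). Usage tables carry optional standard errors and a weighted
variant is available behind the `weights` argument, but the default is
unweighted because the reference analysis plots error bars without stating
a weighted fit. `weight_complexity_r2()` pools all amino-acid × metric
datapoints (metrics min–max normalized — the pooling scale is a package
convention) against free-monomer molecular weights to quantify how much of
the panel is mere mass.

## What the synthetic generators emulate — and what they do not

`gen_metric_table()` draws $X = Z F^\top + \epsilon$ with standard-normal
latent scores and block-structured loadings: graph-framework metrics share
one direction, information-framework metrics a second direction correlated
with the first at `between_cor`. This reproduces the two features the
analysis relies on — strong within-framework correlation and a low-rank
shared covariance that MDS can compress — and, at `noise_sd = 0`, gives
tables of exact known rank for end-to-end recovery tests. Defaults
(`latent_rank = 2`, `noise_sd = 0.05`, `within_cor = 0.8`,
`between_cor = 0.2`) were fixed once as a plausible stand-in for the
observed correlation structure. What the generator does **not** emulate:
the actual values, scales or skewness of real complexity indices, their
discreteness (fractions with small denominators), or any chemically
meaningful gradient — so a green synthetic test establishes that the
machinery is correct, not that the biological conclusion reproduces.
Reproducing the reference tree, Table-1 counts (20/14/8/42) and chronology
requires the article's supplementary metric table, which cannot be bundled
here; the corresponding acceptance test runs when that CSV is supplied at
`inst/extdata/complexity_metrics_16.csv` and reports failure otherwise.

`gen_usage()` is the linear-plus-noise model the regression assumes,
truncated at zero; defaults (intercept 0.08, slope −0.004, noise sd 0.012
on a 0–20 score scale) give usage vectors of realistic magnitude (summing
to ≈ 1) with an $R^2$ in the neighborhood observed for LUCA-level usage.
`gen_random_tree()` draws uniform labelled trees via Prüfer sequences —
used for null-model support and oracles, while the permutation test itself
shuffles labels on a *fixed* topology, matching the reference procedure.

## Degenerate inputs and edge policies

Constant metric columns abort autoscaling (named in the error); pairs with
missing metrics are masked (default), used pairwise, or rejected
(`missing = "fail"`, the main-pipeline setting); zero original distances
are skipped in reconstruction error with a warning; a disconnected ε-graph
is an error advising a larger ε; `min_dimension()` falls back to $n-1$
with a warning when the threshold is unreachable; kappa indices with zero
path counts are `NA`, and any `NA` component makes a Euclidean composite
`NA`.

## In-package versus ingested indices

Only indices fully determined by the hydrogen-suppressed graph plus atom
annotations are computed here (total walk count and its log, Zagreb pair,
Kier kappa triple, Balaban J, chirality/sp³ fractions, Euclidean
composites). The remaining published indices (assembly, synthetic-
accessibility and information scores obtained from external tools) are
ingested as table values and never recomputed. Symmetry-modified walk and
Zagreb variants are an extension point: the modification procedures are
not printed in the source material, so the plain indices are computed and
the pipeline consumes supplied table values.

## Known limitations

* The full-reproduction path is data-gated (see above); without the
  supplementary table the package demonstrates the method on synthetic and
  toy data only.
* Graph edit distance between trees is not implemented (the reference used
  an anytime approximation); Jaccard and adjacency similarity cover tree
  comparison.
* Only the standard genetic code is built in; alternative codes enter via
  a user CSV, and codon-usage or transition/transversion weighting is out
  of scope for the permutation test (an external substitution matrix
  comparison is provided instead).
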