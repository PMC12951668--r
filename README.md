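# codechron

Tools for reconstructing a **molecular-complexity-based chronology of amino
acid recruitment into the standard genetic code**, for researchers in
genetic code evolution, molecular evolution and origins-of-life chemistry.

The premise: each of the 20 proteinogenic amino acids can be placed in a
*complexity space* whose coordinates are its values under a panel of
molecular complexity indices (graph-theoretic: walk counts, Zagreb, Kier
kappa, Balaban J, ...; information-theoretic: chirality and hybridization
fractions, synthetic-complexity scores, ...). Distances in that space,
combined with the mutational structure of the genetic code, let one ask
whether the code recruited amino acids along a gradient of increasing
structural complexity.

## The method

Given a table of complexity values `x` (20 amino acids × p metrics):

1. **Autoscale** each metric to zero mean, unit variance, and form the
   Euclidean distance matrix `d_ij = sqrt(Σ_k (x_ik − x_jk)²)`.
2. **Embed** with classical (Torgerson) MDS — double-center `−½ J D² J`,
   truncate the spectral decomposition — at the smallest dimension giving a
   mean relative reconstruction error below 2%.
3. Build the **ε-neighborhood graph** (the 1-skeleton of a Vietoris–Rips
   complex), increasing ε on a grid until all 20 amino acids form one
   component (ε is expressed per dimension; total threshold = ε × dim).
4. Extract the **minimum spanning tree** (Prim's algorithm) on the original
   pairwise distances; unique when all distances are distinct.
5. Read the **chronology** as cumulative root-to-node distance from glycine
   (the least complex residue).
6. Test **mutational enrichment**: sum single-point codon interchange
   counts `S_{i→j}` over the 19 tree edges, per codon position, and compare
   against (a) `N = 10⁵` random reassignments of amino acids to the fixed
   topology (95% CI `μ ± 1.96 σ/√N`) and (b) the path-graph closed form
   `E(p) = 19 · B(p)`, where `B(p)` is the per-pair background mean —
   83/190, 88/190, 25/190 at positions 1–3 for the standard code (0.44,
   0.46, 0.13 at two decimals).
7. Optionally regress an external amino-acid **usage vector** (e.g. an
   inferred LUCA proteome composition) on the chronology score (OLS, R²,
   two-sided slope test).

All stages are exposed as plain functions (`autoscale`, `distance_matrix`,
`classical_mds`, `build_neighbor_graph`, `prim_mst`, `root_to_node`,
`randomize_assignments`, `ols_fit`, ...) plus a one-call orchestrator
`run_pipeline()`. Seed-deterministic generators (`gen_metric_table`,
`gen_usage`, `gen_random_tree`, `gen_path_alkane`) emulate the statistical
structure the analysis assumes, so the whole pipeline is testable without
external downloads.

## Worked example

```r
library(codechron)
tb  <- gen_metric_table(seed = 11, noise_sd = 0.3)   # synthetic 20 x 16 table
rep <- run_pipeline(tb, run_config(n_trials = 1e4, seed = 1))
print(rep)
#> <codechron_report>
#>   metrics: 16  embedding dim: 8 (mean rel. err 0.01598)
#>   eps_per_dim: 0.55  graph edges: 85
#>   MST total weight: 45.7474
#>   chronology: G M Q S H C N I L F V T W A R P E K D Y
#>   observed mutation counts: 2 / 7 / 4 / 13 (pos 1/2/3/total)
print(rep$randomization)
#> <randomization_result> N = 10000 label permutations
#>  position observed    mean     sd  ci_low ci_high enriched
#>         1        2  8.2625 4.6556  8.1713  8.3537    FALSE
#>         2        7  8.8086 4.0084  8.7300  8.8872    FALSE
#>         3        4  2.5450 2.9573  2.4870  2.6030     TRUE
#>       ALL       13 19.6161 6.2137 19.4943 19.7379    FALSE
```

Reading the output: the synthetic table needed 8 MDS dimensions for <2%
mean distance distortion; the graph first became connected at ε = 0.55 sd
per dimension; the chronology is the root-to-node order from glycine. The
null means sit at their closed forms (19.6 total, 8.8 at position 2) — for
a *random* table the observed counts are not enriched, which is exactly
what the null should say; enrichment (as in the reference analysis, 42
observed vs 19.600 ± 0.038) is a property of the real complexity data.

Codon-level queries work stand-alone:

```r
count_single_point("K", "N")     # 4 (all at position 3)
mutation_fraction("F", "L")      # 6/18 = 0.333...
sapply(1:3, background_per_pair_mean)  # 0.4368 0.4632 0.1316
path_graph_null()                # 8.3 8.8 2.5 19.6
```

## Layout

- `R/` — genetic-code combinatorics, molecular-graph indices, complexity
  space, MDS, tree inference, enrichment statistics, usage association,
  synthetic data, pipeline.
- `tests/testthat/` — unit + property tests with independent oracles
  (exhaustive enumeration, igraph, Biostrings, ape, `cmdscale`);
  `test-acceptance.R` holds the acceptance criteria.
- `vignettes/complexity-chronology.Rmd` — methods notes: model,
  assumptions, parameter choices, what the synthetic generators do and do
  not establish.
- `inst/scripts/codechron.R` — minimal CLI front end.
- `inst/extdata/` — hand-computable toy fixture (`toy_metrics6.csv`),
  decane example graph.
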