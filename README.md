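# homst — high-order minimum spanning tree functional connectivity classification

`homst` is an R package for two-group classification of subjects from
regional brain time series (ROI × time matrices, e.g. atlas-parcellated
resting-state fMRI), aimed at researchers studying *dynamic* functional
connectivity. Instead of classifying on static correlations, it works on the
correlation-of-correlations level:

1. **Sliding windows** cut each ROI series into
   `K = floor((M − N)/S) + 1` overlapping segments; each window yields a
   low-order `R × R` Pearson correlation network.
2. Every unordered ROI pair `(i, j)` traces a **correlation time series**
   across windows; with `P = R(R−1)/2` pair-nodes, the **high-order
   network** is the `P × P` matrix `H[(i,j),(p,q)] = corr(y_ij, y_pq)` —
   large when two couplings fluctuate together (up to four ROIs interacting).
   At the conventional full scale (`R = 90`, `M = 238`, `N = 90`, `S = 1`)
   this is a 4005-node network.
3. Descending-order **Kruskal** reduces `H` to its strongest-weight spanning
   tree (4004 edges at full scale) — the "minimum spanning tree" backbone of
   the MST brain-network literature.
4. Two feature families are extracted: per-node tree metrics (degree,
   eccentricity, betweenness centrality) screened by Kolmogorov–Smirnov
   tests with Benjamini–Hochberg correction, and **discriminative frequent
   subgraphs** mined per group with gSpan (canonical minimum DFS codes) and
   scored by `S(g) = fq(g | G_pos) − fq(g | G_neg) ∈ [−1, 1]`.
5. A **multikernel SVM** combines a normalized linear kernel on the selected
   metrics with a normalized Weisfeiler–Lehman subtree kernel on each
   subject's pattern-restricted tree subgraph:
   `k = a·k_vec + (1−a)·k_graph`, the weight `a` grid-searched over
   `0, 0.1, …, 1` inside the training folds.

A seeded synthetic-cohort generator with group-modulated coupling dynamics
makes the whole pipeline testable without any imaging data; see the methods
vignette (`vignettes/homst-methods.Rmd`) for the model, default parameters
and design rationale.

## Worked example

```r
library(homst)

cc <- cohort_config(n_per_group = 8, R = 8, M = 96,
                    effect_pairs = list(c(1, 2), c(3, 4), c(5, 6)),
                    effect_size = 0.9, noise_sd = 0.2, seed = 42)
cohort <- generate_cohort(cc)

# per subject: windows -> low-order stack -> pair series -> high-order
# network -> spanning tree -> node metrics
features <- extract_features(cohort, N = 24, S = 3)
head(tree_metrics(features$trees[[1]]), 3)
#>   node label degree eccentricity betweenness
#> 1    1   1_2      1           14   0.0000000
#> 2    2   1_3      3           11   0.2706553
#> 3    3   1_4      1           14   0.0000000

report <- cross_validate(features,
  eval_protocol(a_grid = seq(0, 1, 0.25), cost_grid = c(1, 10),
                inner_folds = 4, fq_pos = 0.4, fq_neg = 0.3,
                k_patterns = 8, wl_h = 2, seed = 1))
report
#> accuracy 0.8750  sensitivity 1.0000  specificity 0.7500  AUC 0.8281
```

The report is a nested leave-one-out evaluation: feature selection, subgraph
mining and kernel construction are redone inside every (class-balanced)
training fold, so the accuracy is an honest estimate. Sixteen subjects with
a strong injected dynamic effect are classified at 88% accuracy (AUC 0.83); the group
difference is purely dynamic — static whole-series correlations are matched
by construction — so this number certifies the high-order pathway. At the
package's default study conditions (20 + 20 subjects, `R = 10`, `M = 120`,
`effect_size = 0.8`) the same protocol reaches accuracy ≥ 0.9.

`run_pipeline(config, out_dir)` executes the same stages from a config list
or YAML file and writes every intermediate artifact (cohort CSVs, tree and
metric TSVs, selection and pattern tables, `report.json`, a manifest with
checksums). `inst/cli/homst.R` exposes the stages as shell subcommands
(`simulate`, `network`, `tree`, `select`, `mine`, `classify`, `run`).

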