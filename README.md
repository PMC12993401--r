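# longconn

Paired longitudinal analysis of functional brain-network topology in R.

Clinical neuroimaging studies increasingly ask whether an intervention
(neurosurgery, ablation, stimulation, pharmacotherapy) reorganizes the
brain's functional network. The standard analysis — used across the
resting-state fMRI literature — parcellates the brain into ROIs, correlates
ROI time series, binarizes the connectivity matrix over a range of sparsity
thresholds, and compares graph-theoretic summaries between sessions.
`longconn` implements that entire stack as a tested, reproducible pipeline
for paired (baseline vs follow-up) designs, together with a synthetic
cohort generator so every stage can be validated against a known ground
truth without any patient data.

## What it computes

Starting from ROI-by-time matrices (one per subject per session):

* **Connectivity**: Pearson correlation of all ROI pairs, Fisher r-to-z,
  negatives zeroed — `fc_matrix()`, `cohort_fc()`.
* **Binarization across a sparsity grid** (default 0.05–0.50, step 0.01):
  at density *s* the `round(s·N(N−1)/2)` strongest connections become
  edges, with deterministic tie-breaking and nested edge sets —
  `binarize_stack()`. An admissibility report checks average degree > 2·ln N
  and small-worldness σ > 1.1 across the grid — `admissibility_check()`.
* **Graph metrics per density**: clustering coefficient Cp, characteristic
  path length Lp, global/local efficiency (Eg, Eloc), slice modularity Q,
  plus normalized small-world indices γ = Cp/⟨Cp_rand⟩, λ = Lp/⟨Lp_rand⟩,
  σ = γ/λ against degree-preserving rewired null ensembles; nodal degree,
  nodal efficiency and normalized betweenness — `metric_curves()`,
  `small_world_normalize()`, `rewire_preserving_degree()`.
* **AUC summaries** over the grid (trapezoid) — `curve_auc()`.
* **Modular analysis at density 0.15**: group-mean baseline graph, greedy
  community detection, per-subject intra/inter-module edge counts against
  the fixed group partition, participation coefficients, and a restricted
  nodal analysis over the modules implicated by inter-modular trends —
  `group_graph()`, `detect_communities()`, `module_edge_counts()`,
  `participation_coef()`.
* **Paired statistics**: Shapiro–Wilk-gated paired t / Wilcoxon signed-rank
  tests, one-tailed uncorrected for the global AUC family (directions fixed
  a priori), two-tailed with Benjamini–Hochberg FDR for nodal and modular
  families, trend flags at uncorrected p < 0.05, and Spearman correlations
  with clinical tremor scores — `run_statistical_plan()`.
* **Synthetic paired cohorts** with planted modular structure, hubs, and a
  follow-up effect (block-correlated multivariate normal, PSD-projected) —
  `cohort_design()`, `design_preset()`, `simulate_cohort()`,
  `simulate_clinical()`, `write_cohort()`/`read_cohort()`.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

```r
library(longconn)

# 20 subjects x 2 sessions, 90 ROIs in 6 modules, with a planted follow-up
# effect on module pairs (2,4) and (2,6) and three hub ROIs in module 2.
# The grid starts at 0.12, the sparsest density satisfying the 2 ln N
# average-degree criterion at N = 90.
report <- run_pipeline(
  design = design_preset("test", "planted"),
  grid = sparsity_grid(0.12, 0.42, 0.10),
  nulls = null_config(n_nulls = 5),
  seed = 1
)
report
#> <longconn_report>
#>   cohort: 20 subjects x 2 sessions, 90 ROIs
#>   admissibility: 40/40 pass the average-degree criterion
#>   partition: 6 modules, Q = 0.833
#> <stat_plan>
#>   global (one-tailed, uncorrected): 8 metric(s), 6 with p < 0.05
#>   nodal (two-tailed, FDR per metric): 270 tests, 99 FDR-significant
#>   module pairs: 15 inter (11 trend), 6 intra (6 trend)
#>   restricted nodal family: 360 tests over modules {1,2,3,4,5,6}, 153 FDR-significant
#>   correlations: 122 Spearman test(s)
#>   seed: 1

dplyr::filter(report$plan$module_inter, trend, mean_diff > 0)[,
  c("item", "p_raw", "p_fdr", "mean_diff")]
#>        item        p_raw        p_fdr mean_diff
#> 1 module2&4 9.769310e-10 7.326983e-09        56
#> 2 module2&6 9.189553e-11 1.378433e-09        64

bc <- dplyr::filter(report$plan$restricted, metric == "betweenness")
head(bc[order(bc$p_raw), c("node", "module", "p_raw", "p_fdr", "mean_diff")], 3)
#>   node module        p_raw        p_fdr  mean_diff
#> 1   16      2 1.984848e-07 1.295584e-05 0.02754001
#> 2   17      2 2.879076e-07 1.295584e-05 0.02686689
#> 3   18      2 5.441717e-07 1.632515e-05 0.02716453
```

Reading the output: the group baseline graph decomposes into the six
planted modules (Q = 0.833); the two module pairs carrying the planted
coupling increase — and only those among the pairs with increased counts —
are flagged with strong paired evidence (mean gains of 56 and 64 edges at
density 0.15); and the three nodes with the largest betweenness increases
in the restricted family are exactly the three planted hub ROIs (nodes
16–18, the first three ROIs of module 2). `write_run_report(report, dir)`
writes every table as plain CSV/TSV/JSON; re-running with the same seed
reproduces them byte-for-byte.

The `"full"` preset scales the same pipeline to the full emulated study
design (37 subjects, 273 ROIs = 246 cerebral + 27 cerebellar, 250 time
points, 46-density grid).

## Documentation

The methods vignette (`vignettes/longconn-methods.Rmd`) describes the
model, the synthetic generator and what it does and does not emulate, all
numerical conventions (rounding, tie-breaking, disconnected-graph
handling, Wilcoxon zero/tie policy, FDR family scopes), and the simulation
scales used by the test suite.
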