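---
title: "Methods: paired small-world and modular analysis of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired small-world and modular analysis of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longconn)
library(dplyr)
```

## What the package computes

`longconn` implements a longitudinal (baseline vs follow-up) graph-theoretic
analysis of resting-state functional brain networks, starting from
parcellated ROI time series. The pipeline is the standard binary-network
stack used in clinical connectomics:

1. **Connectivity.** Pairwise Pearson correlation between ROI time series,
   Fisher r-to-z transformed, negative values set to zero (their
   physiological meaning in resting-state data is contested), diagonal
   zeroed.
2. **Binarization across a sparsity grid.** For each density $s$ in a grid
   (default $0.05$ to $0.50$ in steps of $0.01$), the
   $K = \operatorname{round}(s\,N(N-1)/2)$ strongest connections become
   edges. Edge sets are nested along the grid by construction.
3. **Global metrics per density.** Clustering coefficient $C_p$,
   characteristic path length $L_p$, global and local efficiency
   ($E_g$, $E_{loc}$), modularity $Q$ of the slice's greedy partition, and
   the small-world indices $\gamma = C_p / \langle C_p^{rand}\rangle$,
   $\lambda = L_p / \langle L_p^{rand}\rangle$,
   $\sigma = \gamma / \lambda$, with the random reference an ensemble of
   degree-preserving (Maslov–Sneppen double-edge-swap) rewirings.
4. **Nodal metrics per density.** Degree, nodal efficiency, and normalized
   Brandes betweenness.
5. **AUC summarization.** Every metric curve is integrated over the density
   grid (trapezoid rule), giving one threshold-robust number per metric per
   subject-session.
6. **Modular analysis at a single density (0.15).** Baseline connectivity
   matrices are averaged, the group mean is binarized at density 0.15, and
   communities are detected by greedy agglomerative modularity maximization.
   With the group partition held fixed, each subject-session's 0.15-density
   graph is reduced to a module-block edge-count matrix (intra-module
   diagonal, inter-module off-diagonal), and participation coefficients are
   computed per node.
7. **Statistics.** Paired follow-up vs baseline comparisons with a
   Shapiro–Wilk gate (normal differences use the paired t-test, otherwise
   the Wilcoxon signed-rank test), one-tailed and uncorrected for the global
   AUC family, two-tailed with Benjamini–Hochberg FDR for nodal and modular
   families, trend flags at uncorrected $p < 0.05$, a restricted nodal
   family over the modules implicated by inter-modular trends, and Spearman
   correlations against clinical tremor scores.

An admissibility report accompanies every run: the sparsity range is
considered adequate when the average degree at the sparsest density exceeds
$2\ln N$ (11.22 for $N = 273$) and small-worldness stays above
$\sigma > 1.1$ across the grid.

## The synthetic paired cohort

No patient data ships with the package. Instead, a generator produces
paired cohorts with a known ground truth, which is what every simulation
and acceptance check runs on.

The generative model is a block-structured multivariate normal: ROIs are
partitioned into $K$ modules; the latent correlation is `rho_within` inside
modules and `rho_between` between them; the observation covariance is the
latent correlation plus `noise_sd`$^2$ on the diagonal (so observed
correlations are attenuated by $1/(1+\texttt{noise\_sd}^2)$). A follow-up
effect is planted two ways: designated module *pairs* gain `delta_rho`
coupling, and designated *hub* ROIs gain `delta_hub` on all their
cross-module couplings (capped strictly below `rho_within`). Matrices are
projected to the nearest positive semi-definite correlation matrix
(eigenvalue clipping, diagonal rescaling) whenever the planted structure
requires it. Each subject receives a small uniform jitter ($\pm 0.03$) on
both rho levels, shared across their two sessions, plus an effect-size
scale drawn from $\mathrm{Unif}(0.7, 1.3)$ that multiplies both deltas; the
same scale drives the synthetic clinical improvement so that
clinical–topology correlations carry a planted signal rather than being
vacuously null.

### Default study conditions

The `"full"` preset emulates the study design the pipeline targets: 37
subjects $\times$ 2 sessions, 273 ROIs (246 cerebral + 27 cerebellar) in six
modules of sizes 31/33/77/18/69/45, 250 time points per scan. The `"test"`
preset, used throughout the test suite, scales this to 20 subjects, 90 ROIs
(six modules of 15, the last cerebellar), and $T = 150$.

Parameter defaults and their rationale:

* `rho_within = 0.35`, `rho_between = 0.10`. At 90 ROIs and the modular
  density 0.15 the edge budget is 601 edges while the within-module pairs
  number 630. With very strong within-module correlation (0.5 and above)
  the budget saturates on within-module pairs, inter-modular counts
  degenerate to near zero, and module-pair statistics become meaningless.
  At 0.35, sampling noise ($\mathrm{sd}(z) \approx 1/\sqrt{T-3}$) lets a
  realistic minority of inter-modular connections into each subject's
  graph, which is how real functional connectomes behave.
* `noise_sd = 0.3`: mild attenuation (about 8%), representing scanner and
  physiological noise left after preprocessing.
* `delta_rho = 0.15` on module pairs (2,4) and (2,6), `delta_hub = 0.12` on
  three hub ROIs in module 2: effects large enough that a 20-subject paired
  design detects them reliably, mirroring a treatment study powered for its
  primary endpoint.
* Jitter $\pm 0.03$: between-subject variability that leaves the block
  structure intact. The magnitude is a free parameter of the generator;
  nothing in the emulated design pins it down, so it is exposed in
  `cohort_design()` rather than hard-coded.

### What the generator does not emulate

There is no hemodynamic forward model, no motion or physiological noise
structure, no spatial autocorrelation, and no volumetric geometry; time
points are i.i.d. draws, whereas real BOLD series are autocorrelated
(reducing the effective $T$). Passing tests therefore demonstrate that the
pipeline's *computations* are correct and that its statistical layer
behaves as designed under a faithful modular-correlation model — not that
any particular clinical effect would replicate in real data.

## Numerical choices

* **Logarithm in the admissibility threshold.** $2\log N$ is read as the
  natural logarithm: $2\ln 273 = 11.22$, matching the printed criterion.
* **Edge-count rounding.** Nearest integer, ties half-up (`floor(x + 0.5)`),
  applied to $s\,N(N-1)/2$.
* **Ties at the sparsity cut** break deterministically: value descending,
  then row index, then column index. Reruns are bit-identical across
  platforms.
* **Perfect correlations.** Off-diagonal $|r| = 1$ is clipped to
  $1 - 10^{-7}$ before `atanh` (with a warning); real data never reaches it,
  but degenerate synthetic inputs must not produce infinite weights.
* **Scarce positive entries.** If a requested density exceeds the number of
  strictly positive connections, all positive edges are kept and the
  achieved density is recorded in the stack.
* **Disconnected graphs.** $L_p$ averages finite pairs only and records the
  number of unreachable pairs; $E_g$ treats unreachable pairs as zero
  efficiency. Null ensembles use the same convention.
* **Betweenness** is reported in normalized form (divided by
  $(N-1)(N-2)/2$); normalization rescales paired statistics without
  changing their p-values.
* **Community detection** uses deterministic greedy agglomerative
  modularity maximization (igraph's fast-greedy merging); modularity $Q$ of
  the returned assignment is computed by the package's own definitional
  implementation, $Q = \sum_i (e_{ii} - a_i^2)$. Exhaustive-search oracles
  on small graphs and planted-partition recovery checks validate the
  optimizer. Partitions with $Q \ge 0.3$ are flagged as non-random.
* **Wilcoxon signed-rank**: zero differences are dropped (Wilcoxon's
  convention); the exact null distribution is used for up to 25 tie-free
  non-zero differences, the continuity-corrected normal approximation
  otherwise.
* **One-tailed directions** for the global family are fixed a priori by the
  hypothesis that treatment shifts the network toward a more efficient,
  small-world configuration: $\sigma, \gamma, C_p, E_g, E_{loc}$ expected
  to increase, $L_p, \lambda$ and $Q$ (reduced segregation) to decrease.
  The table is data-independent and recorded in every result bundle.
* **FDR family scopes**: across nodes per metric for the whole-brain nodal
  family; across the 15 inter-module pairs and, separately, the 6
  intra-module counts; across the restricted node set per metric for the
  implicated-module family. Globals are uncorrected (standard practice for
  a small a priori family, at a known cost in type-I risk).
* **Seeding.** Every random draw (cohort, clinical scores, each null
  ensemble of each density slice) derives deterministically from one master
  seed via a fixed integer-mixing function, so reports regenerate
  bit-identically.

## Design decisions on open points

* **Inter/intra-modular "connectivity" is counted as binary edges** at
  density 0.15 against the fixed baseline partition. The magnitudes this
  produces (intra-module counts scaling with module size squared, totals
  equal to the 0.15 edge budget) match the reported scale of such tables,
  whereas summed z-weights would not.
* **The partition is estimated once from baseline** and held fixed for both
  sessions, so longitudinal comparisons are made against a common modular
  frame.
* **Implicated modules** are those appearing in any inter-pair with an
  uncorrected paired $p < 0.05$ (a trend), and the restricted nodal family
  is scoped to their union.
* **Nodal values entering the restricted family** are AUCs over the grid
  (consistent with the whole-brain nodal analysis); participation is
  computed at 0.15 only, since it requires the partition's density.
* **Null ensembles** default to `n_nulls = 100` in production use and are
  scaled down in simulations; under the null of exchangeable sessions the
  paired tests remain exactly level regardless of ensemble size, so
  replicate simulations use small ensembles.

## Simulation scales used by the test suite

The package's replicate simulations run at deliberately compact sizes,
chosen once as part of the study design emulation:

* **Type-I control**: 200 null cohorts (20 subjects, 90 ROIs, $T = 150$,
  densities 0.10/0.25/0.40, 3 nulls per slice). With no planted
  effect the two sessions are exchangeable, so each one-tailed global test
  should reject at the nominal 5% rate; the observed rate over
  $200 \times 8$ correlated tests is required to sit within $\pm 0.03$.
* **Effect recovery**: 50 planted-effect cohorts (densities 0.10/0.25/0.40).
  The planted module pairs must be flagged as trends and rank first among
  all 15 pairs by paired evidence, and the node with the largest
  betweenness-AUC increase in the restricted family must be a planted hub,
  each in at least 80% of replicates.

## Worked example

```{r example, eval = FALSE}
library(longconn)

# grid starts at 0.12: the sparsest density that satisfies the 2 ln N
# average-degree criterion at N = 90 ROIs (s >= 2 ln 90 / 89 = 0.101)
report <- run_pipeline(
  design = design_preset("test", "planted"),
  grid = sparsity_grid(0.12, 0.42, 0.10),
  nulls = null_config(n_nulls = 5),
  seed = 1
)
report
glance(report)

# the families of the statistical plan
tidy(report$plan)

# module-level evidence
dplyr::filter(report$plan$module_inter, trend)

# write all artifacts as plain text
write_run_report(report, "run1")
```

The `"full"` preset (37 subjects, 273 ROIs, the 46-density grid, 100 nulls
per slice) runs the identical code path and is a matter of hours on one
CPU.

## Known limitations

* All metrics are binary-graph metrics; weighted variants, rich-club
  analysis, and negative-edge treatments other than clipping are out of
  scope, as are consensus or multi-resolution community methods.
* The greedy optimizer returns a deterministic, validated partition but —
  like all modularity maximizers — is a heuristic; on graphs where the
  modularity landscape is flat the partition can differ from other
  optimizers' output.
* The statistical layer implements paired univariate tests with FDR; it
  does not provide mixed-effects models, covariate adjustment, or
  permutation-based network statistics.
* Clinical scores are synthetic and linearly coupled to the planted effect
  scale; they validate the correlation machinery, not any clinical claim.
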