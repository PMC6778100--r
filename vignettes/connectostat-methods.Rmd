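---
title: "Group analysis of functional connectomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group analysis of functional connectomes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectostat)
```

## The analysis problem

Resting-state fMRI connectomics asks whether the *organization* of whole-brain
functional connectivity differs between groups of subjects. Each subject
contributes a T x N matrix of regional (ROI) time series; pairwise Pearson
correlation turns this into an N x N functional-connectivity matrix; graph
construction turns the matrix into a binary network whose topology can be
summarized and compared. `connectostat` implements this chain for
multi-group case-control designs, with two complementary inference branches:

1. **Global topology.** Mean clustering coefficient (segregation), global
   efficiency (integration) and degree assortativity (resilience) are
   computed on binary graphs across a sweep of network densities, and groups
   are compared per density with permutation two-sample t-tests under
   Benjamini-Hochberg FDR control across the sweep. Rich-club coefficients,
   normalized against degree-preserving random networks, probe the wiring
   among hub regions specifically.
2. **Local connectivity.** The network-based statistic (NBS) finds connected
   components of edges whose group difference exceeds a primary threshold,
   and controls the family-wise error rate by comparing each component's
   extent to the permutation null distribution of the maximal component
   size.

Raw image processing (registration, nuisance regression, band-pass
filtering, parcellation) is out of scope: the pipeline starts at extracted
ROI time series, plus an atlas table giving each ROI's coordinates in mm.
The motion-QC summaries that accompany such analyses (mean absolute
displacement and mean scan-to-scan displacement from the rigid-body
translation parameters) are provided by `compute_displacement()`; we take
the mean of per-volume Euclidean norms (not the root-mean-square), and use
translations only, since that is what the displacement definition names.

## Connectome construction

`correlation_matrix()` computes pairwise Pearson correlations with the
diagonal zeroed. The Fisher z-transform (`fisher_z = TRUE`, the default in
the pipeline) is applied *before* covariate regression because atanh(r) is
variance-stabilizing, which makes the per-edge ordinary-least-squares
residualization across subjects better behaved; it is toggleable because
analyses on the raw r scale are also common.

Three masks restrict the analyzable edge set:

* **Distance exclusion** (`distance_mask()`, default 20 mm): node pairs
  strictly closer than the threshold are removed, since spatial smoothing
  induces artifactual short-range correlations. A pair at exactly the
  threshold distance is kept ("less than" is strict).
* **Reference positive mask** (`reference_positive_mask()`, default density
  0.45): the control-group average matrix is zeroed at negative entries and
  the strongest edges are kept down to the requested fraction of all
  N(N-1)/2 node pairs. Using a single reference mask gives every subject the
  same network support, which edge-wise group tests require.
* **Positivity**: only positive (masked) correlations are candidates for
  thresholding; analyses focus on differences in positive coupling.

`proportional_threshold()` retains the floor(S * N(N-1)/2) strongest
candidate edges at density S and binarizes. Density is always defined on the
full N(N-1)/2 denominator, even when masking leaves fewer candidates; if the
mask binds, all remaining candidates are kept, a warning is raised and the
achieved density is recorded in an attribute rather than silently
redefined. Ties between equal weights are broken by (i, j) node-index order
so that results are bit-reproducible; with continuous correlation values
ties have measure zero, so this choice cannot bias real analyses. Edge sets
are nested across the density grid by construction, which the tests verify
(thresholding monotonicity).

Covariate control (`regress_covariates()`) residualizes every edge on an
intercept plus column-centered covariates (age, gender, site dummy codes)
and adds the fitted intercept back, preserving each edge's grand mean. Site
enters as a fixed covariate; no mixed-effects site model is attempted. With
an empty covariate set the operation is exactly the identity.

## Graph metrics and their conventions

All metrics operate on undirected binary adjacency matrices and are
invariant under node relabeling.

* **Mean clustering**: per-node C_i = 2 t_i / (k_i (k_i - 1)), with C_i = 0
  for nodes of degree < 2, averaged over *all* nodes (the Brain
  Connectivity Toolbox convention). The alternative -- averaging only over
  nodes where C_i is defined -- changes values on sparse graphs, so the
  convention matters and is fixed here.
* **Global efficiency**: mean inverse shortest-path length over ordered
  pairs; unreachable pairs contribute 0, so the sparsely thresholded,
  possibly disconnected graphs that a 10% density produces are handled
  without error.
* **Assortativity**: Pearson correlation of end-point degrees over the
  directed edge list. On regular graphs the end-point degree variance is 0
  and the coefficient is undefined; this is returned as `NA`, never as a
  silent 0, and downstream tests drop such values pairwise with a logged
  count rather than imputing them.

The density sweep runs from 10% to 34% in steps of 1% (25 densities) by
default -- a range wide enough to cover the small-world regime of typical
functional connectomes while avoiding the fragmentation below 10% and the
noise-edge saturation above ~35%.

## Rich-club analysis

The rich-club coefficient at degree level k is the edge density among nodes
of degree *strictly greater* than k (the standard rich-club convention for
"the kth subgraph"): Phi(k) = 2 E_k / (N_k (N_k - 1)), undefined when fewer
than 2 nodes qualify. Because Phi(k) rises mechanically with k even in
random graphs, it is normalized by the mean coefficient over R
degree-preserving randomizations (Maslov-Sneppen double-edge swaps,
`swap_factor = 10` attempted swaps per edge by default -- enough rewiring
effort to decorrelate graphs of the sizes used here, and configurable for
larger ones). A one-tailed permutation p-value per k,
p(k) = (1 + #{Phi_rand(k) >= Phi(k)}) / (1 + R), is Bonferroni-corrected
over the evaluated k levels; the **rich-club regime** is the maximal
contiguous run of k with Phi_norm(k) > 1 and a surviving p-value. The +1
correction means p can never be exactly 0; consequently the number of
evaluated k levels bounds what R can resolve -- with R = 200 nulls the
smallest attainable p is 1/201, so Bonferroni detection is only possible
when at most ~10 k levels are evaluated. Group-level rich-club analysis
therefore uses R = 1000 by default.

Group comparisons of rich-club organization are made on *group-average*
networks thresholded at the top 7% of strongest positive connections
(optionally swept from 7% to 15% as a stability check). The observed
difference Delta(k) = Phi_g1(k) - Phi_g2(k) is referred to a null of R
differences between paired degree-preserving randomizations of the two
graphs, two-tailed, BH-FDR corrected across k. Because an ER graph
conditioned on its degree sequence is (approximately) uniform over graphs
with that degree sequence, this randomization null closely tracks the
sampling variability of Delta under exchangeability; empirically the test
is mildly *conservative* (per-k rejection a little below the nominal 5% in
all-null simulations) due to the +1 correction and the discreteness of
Phi on finite graphs. It is never anti-conservative in our calibration
runs, which is the direction that matters for error control.

## Permutation inference

`permutation_ttest()` residualizes the pooled values on covariates once and
then permutes group labels -- a Freedman-Lane-style simplification chosen
because the exact propagation of covariate refitting through every
permutation is substantially slower and changes little when covariates are
balanced; this choice is documented rather than hidden. When the number of
distinct label arrangements is at most `n_perm` the null is enumerated
exhaustively and the p-value is the exact proportion of arrangements with
|t*| >= |t| (the observed arrangement counts itself); otherwise Monte-Carlo
permutations with the (1 + c) / (1 + n_perm) correction are used. The
two conventions match on small instances to within Monte-Carlo error, which
is tested.

NBS (`nbs_test()`) converts the primary threshold p = 0.005 into a t
quantile at the contrast's degrees of freedom (n - 2 minus the number of
covariates, reflecting the residualization). One-sided contrasts are the
default (`direction = "less"` tests for decreased connectivity in group 1),
with the opposite direction and a two-sided variant available; testing each
direction separately mirrors how decreased- and increased-connectivity
networks are usually reported. The component statistic is the extent (edge
count); an intensity variant is deliberately not implemented. The
permutation stream is fully governed by one seed, and the null distribution
of maximal component extents is returned with the result so that the
monotonicity of FWER p in extent can be inspected directly.

## The synthetic cohort generator

Because raw clinical imaging data cannot ship with the package, the
generator in `cohort_config()` / `sample_cohort()` produces cohorts whose
*population* covariance carries exactly the structure the analyses assume:

* nodes are split into contiguous communities; correlations are `within_r`
  inside and `between_r` across communities;
* a planted effect adds `delta` to a designated edge set in a designated
  group only, so edge-level ground truth is known exactly;
* the matrix is repaired to positive definiteness by flooring eigenvalues
  at 1e-6 and rescaling to unit diagonal -- a simple deterministic repair;
  when it binds, realized correlations deviate slightly from the nominal
  block values (the generator's tests measure recovery against the
  *repaired* population matrix for this reason);
* subjects are drawn i.i.d. from a zero-mean multivariate normal with their
  group's covariance plus independent observation noise; per-subject seeds
  are derived from the master seed and the subject index, so enlarging a
  cohort never reshuffles existing subjects;
* covariates follow fixed, documented distributions: age ~ Uniform(20, 55)
  years, gender ~ Bernoulli(0.5) coded 0/1, site assigned round-robin over
  two sites. They are intentionally not configurable, keeping the test
  surface stable.

Atlases (`generate_atlas()`) place ROI centres in a brain-sized ellipsoid
(semi-axes 70/85/60 mm) with a minimum separation of 8 mm, so that the
20 mm exclusion removes a realistic fraction of short-range pairs.

What the generator does *not* emulate: hemodynamic response and BOLD
autocorrelation, scanner drift, head motion, or heavy-tailed noise. Passing
tests on synthetic cohorts therefore demonstrate the *statistical
machinery* -- calibration of error rates, recovery of planted effects,
correctness of the graph computations -- not robustness to every artifact of
real fMRI. Effect sizes for planted differences are free parameters of the
simulator; recovery results are properties of the simulator's settings, not
reproductions of any empirical effect size.

## Numerical and degenerate-input choices

* Correlations are clipped to +/-(1 - 1e-12) before atanh so collinear
  series stay finite.
* Constant time-series columns, rank-deficient covariate designs, asymmetric
  matrices, zero-margin contingency tables and edgeless graphs raise
  immediate, named errors; readers reject malformed files (duplicate ROI
  ids, non-numeric coordinates, missing cells) with line/cell references
  rather than coercing.
* Zero-variance edges in the NBS receive t = 0 and are counted; a test
  where both groups are constant and equal returns p = 1 with a warning.
* Matrices round-trip through TSV at 17 significant digits, preserving 12+
  significant digits.

## Simulation sizes used by the test suite

The calibration and recovery suites run at sizes chosen to make their Monte
Carlo error small relative to the bands they check while keeping the whole
suite fast on a single CPU: type-I calibration uses 1,000 null replicates of
10-vs-10 with 999 permutations; NBS family-wise error uses 200 null cohorts
(16 ROIs, 12 subjects per group, T = 60, 500 permutations); NBS recovery
uses 50 cohorts of 30 subjects per group (25 ROIs, T = 150) with a planted
30-edge connected subnetwork whose effect is about two pooled standard
deviations on the Fisher-z scale; rich-club detection uses 50 planted-core
graphs (106 nodes, a 6-node clique core wired into a sparse periphery) and
50 matched ER controls at R = 200 nulls. The planted-core design
deliberately keeps the core degree at 10 so that the number of evaluated
k levels stays within what R = 200 can resolve under Bonferroni correction
(see the rich-club section above).

## Known limitations

* Partial correlation, wavelet/dynamic connectivity and weighted-graph
  metric variants are not implemented; the binary, positive-correlation
  pipeline is the scope.
* Only two-group contrasts are supported in the NBS (no F-test variant).
* Site is a fixed effect; strongly unbalanced multi-site designs may want a
  mixed model, which is out of scope.
* The rich-club difference test inherits the conservatism of discrete
  permutation p-values on small graphs; with R = 1000 this is negligible.
* Whether global metrics should be computed on reference-masked or
  unmasked individual matrices is an open analytic choice; the pipeline
  applies the mask uniformly to both the metric and NBS branches for
  coherence, and `apply_reference_mask = FALSE` restores the alternative.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- list(
  simulate = list(n_rois = 20, n_modules = 4, within_r = 0.45,
                  between_r = 0.1, groups = list(hc = 12, sa = 12),
                  n_timepoints = 120, noise_sd = 0.2),
  control_group = "hc",
  build = list(fisher_z = TRUE, reference_density = 0.5,
               density_grid = c(0.10, 0.34, 0.01)),
  inference = list(n_perm = 1000, R = 1000, p_primary = 0.005,
                   richclub_density = 0.07, direction = "less"),
  seed = 7,
  out = "run-out"
)
res <- run_pipeline(cfg)
res$manifest$n_analyzable_edges
summary(res$nbs$hc_vs_sa)
```

The manifest written alongside the outputs records the package version,
seed, all build and inference parameters, the achieved reference density
and the analyzable edge count -- enough to re-execute the run exactly.
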