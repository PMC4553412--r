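---
title: "Multi-modal brain network efficiency: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal brain network efficiency: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conneff)
```

# The scientific problem

Resting-state brain activity and cortical morphology can each be summarized
as a per-subject graph: nodes are atlas regions (here 264), and edges are
either the correlation of spontaneous activity between regions (functional
connectivity) or the similarity of their gray-matter patterns (morphological
connectivity). Graph efficiency — how short the paths between regions are —
is a compact description of how well such a network supports parallel
information flow, and group differences in efficiency are a standard probe
of network disorganization in disease, for example in Parkinson's disease
with tremor, where both decreases (degeneration) and increases
(compensation) have been reported.

`conneff` implements that full analysis as a tested pipeline: network
construction from both modalities, efficiency quantification against
degree-preserving null models, covariate-adjusted permutation inference,
multivariate classification, and screened regression — exercised end to end
on a synthetic cohort whose effects are planted and therefore recoverable.

# Network construction

## Functional networks: wavelet correlations

Each subject's ROI time series are decomposed with the maximal-overlap
discrete wavelet transform (MODWT), a non-decimated, shift-equivariant
transform whose scale $j$ isolates the frequency band
$[1/2^{j+1},\,1/2^{j}]$ cycles per sample — at TR = 2 s: 0.125–0.25 Hz
(scale 1), 0.0625–0.125 Hz (scale 2), 0.03125–0.0625 Hz (scale 3), and
0.015625–0.03125 Hz (scale 4). The edge between two nodes is the Pearson
correlation of their scale-$j$ detail coefficients.

Choices the transform leaves open, and what this package does:

* **Filter family.** Daubechies least-asymmetric 8-tap (LA8), the de facto
  standard for fMRI wavelet analysis; Haar and D4 are available. The filter
  is configurable because no choice is canonical for short series.
* **Boundary handling.** Periodic (circular) by default, which makes the
  energy decomposition across scales exact; reflection is available.
  Boundary-affected coefficients are retained — at 175 timepoints and
  $J = 4$ trimming would discard most of the series.
* **Depth.** $J = 4$, matching the four bands above; deeper levels are not
  resolvable at 175 timepoints with an 8-tap filter.

A tension worth knowing about: the conventional resting-state band-pass
(0.01–0.1 Hz) removes most of the scale-1 band (0.125–0.25 Hz). The
band-pass stage is therefore a config flag (`do_bandpass`, default on).
Because every node's series passes through the same linear filter,
between-node correlations of spatially mixed white noise are unchanged in
population, so the planted structure remains recoverable at every scale
either way; on real data, scale-1 results obtained with the filter on
should not be interpreted.

## Morphological networks: rotation-maximized seed cubes

Each node is represented by a small cube of gray-matter values
(3×3×3 voxels by default, the seed-cube convention) centered on the node
centroid. The edge between two nodes is the maximum, over the cube's
isometries, of the Pearson correlation between the two flattened cubes —
rotation-maximization makes the similarity insensitive to the local
orientation of cortical folds. Defaults and their reasons:

* **48 isometries** (24 proper rotations plus reflections); a 24-rotation
  mode exists. The maximum over the full isometry group is symmetric in its
  two arguments by group closure; the implementation additionally evaluates
  both directions so symmetry holds exactly in floating point.
* **Positivity filter.** Negative similarities are set to zero before
  thresholding: only positive gray-matter similarity is interpreted as
  morphological connectivity.
* **Zero-variance exclusion.** Cubes with no gray-matter variation cannot
  be correlated; such nodes are excluded per subject and reported. The
  synthetic generator plants a configurable fraction of them (default
  0.01%) to keep this path exercised.
* **One centroid cube per node.** Mapping a voxel-level cube method onto a
  264-region atlas admits several readings (all ROI voxels, ROI-mean
  vectors, centroid cubes); the centroid cube is the minimal one and is the
  documented choice here, not a claim about any particular prior
  implementation.
* **Maximum-statistic bias.** The maximum of 48 correlated correlations is
  biased upward for independent cubes (about +0.3 for 27-voxel cubes, by
  Monte-Carlo in the test suite). Because every edge inherits the same
  bias, ranking-based sparsity thresholding is unaffected, but raw
  similarity values should not be read as plain correlations.

# Topological analysis

Networks are binarized by **sparsity**: at sparsity $s$ the
$\mathrm{round}(s \cdot N(N-1)/2)$ strongest edges are kept, over the grid
$0.02 \le s \le 0.40$ in steps of 0.02 (20 thresholds). Ties at the cut are
broken by (weight, row, column) order so runs are deterministic.

For a binary graph $G$ with $N$ nodes, with $d_{ij}$ the shortest-path
length (disconnected pairs contribute $1/d = 0$):

$$E_{glob}(G) = \frac{1}{N(N-1)} \sum_{i \ne j} \frac{1}{d_{ij}}, \qquad
E_{loc}(G) = \frac{1}{N} \sum_{i} E_{glob}(G_i), \qquad
e_i = \frac{1}{N-1} \sum_{j \ne i} \frac{1}{d_{ij}},$$

where $G_i$ is the subgraph induced by the neighbors of node $i$ (the node
itself excluded), and $E_{glob}$ of a subgraph with fewer than two nodes is
defined as 0. Shortest paths are breadth-first searches implemented in
C++ (each local-efficiency evaluation at 264 nodes runs 264 all-pairs
problems, which a pure-R loop cannot sustain across null ensembles); the
test suite verifies all three metrics exactly against a brute-force
Floyd–Warshall oracle on hundreds of small random graphs.

Curves over the grid are summarized by the trapezoidal **area under the
curve** (AUC), the threshold-free scalar used by all downstream stages.

## Null models and small-worldness

Observed efficiencies are normalized by the mean over an ensemble
(default 100) of degree-preserving rewirings (double-edge swaps, 10
attempts per edge). A network is flagged **small-world** when normalized
local efficiency exceeds 1 while normalized global efficiency is
approximately 1; "approximately" is quantified as $|\cdot - 1| \le 0.1$
(configurable), since the verbal definition carries no number.

Small-world flags are evaluated at the mid-grid sparsities
$\{0.20, 0.25, 0.30\}$ rather than over the whole grid, for a percolation
reason: a network with $m$ equal modules has only about $1/m$ of its node
pairs within modules, so below sparsity $\approx 1/m$ (0.12 for the
default 8 modules) the strongest-edge graph is necessarily fragmented and
normalized global efficiency is dominated by disconnection, not topology.
Any sparsity in the connected regime yields the same qualitative flags.

# Statistical machinery

* **Group comparisons** use Freedman–Lane residual permutation (default
  10,000 permutations): the metric is regressed on the covariates (age,
  gender) pooled, residuals are permuted, and the group-effect statistic is
  recomputed. The scheme is the standard choice when covariates are named
  but no permutation scheme is specified; two-tailed p-values use the
  add-one estimator, so the smallest attainable p is $1/(n_{perm}+1)$.
  The suite verifies type-I error of 5% ± 2% under the null.
* **Multiple comparisons** across nodes use the $p < 1/N$ false-positive
  rule ($1/264 \approx 0.0038$).
* **Partial correlation** between network metrics and clinical scores
  adjusts both variables for age and gender; p comes from the t
  distribution with $n - k - 2$ degrees of freedom.
* **Classification** feeds AUC nodal efficiency into maximum-uncertainty
  LDA (MLDA): the pooled within-class covariance has its eigenvalues
  floored at their mean, which keeps the model well-posed when features
  outnumber subjects. Validation is leave-one-out, and — deliberately —
  **feature screening runs inside every fold**: screening once on the full
  sample leaks the held-out subject into selection and inflates accuracy.
  The optimistic variant is available as `screen_once = TRUE` for
  comparison only. Significance is a z-score against 100 full LOOCV runs on
  permuted labels. Class priors are equal despite the 16/20 imbalance
  (configurable).
* **Regression** screens candidate predictors by Pearson correlation with
  the response (p < 0.01) and fits ordinary least squares on the survivors.
  Screening and fitting share the same sample — that is the procedure being
  modeled, and it is optimistic at small n: with 264 null candidates at
  n = 16, some predictor passes screening in most cohorts, and any survivor
  alone forces $R^2 \ge t_{crit}^2/(t_{crit}^2 + n - 2) \approx 0.39$. The
  test suite quantifies this null distribution rather than silently
  "fixing" the procedure; reported $R^2$ values from this stage should be
  read against it.

# The synthetic cohort

The generator emulates the study design: 20 controls + 16 patients, 264
nodes in 8 equal modules, 180 volumes at TR = 2 s (5 discarded), block
target correlations 0.5 within modules and 0.1 between, and a
**topology gap** of −0.15 added to the patients' intra-module coupling —
weaker within-module coupling lowers the patients' local-efficiency curves,
the planted direction of the group effect. Time series are Gaussian noise
colored by the symmetric square root of the group covariance (an AR(1)
knob exists, default off, so wavelet-scale correlations are analytically
flat across scales). Gray-matter cubes are module archetypes plus subject
noise (sd 0.5), so the morphological modules mirror the functional ones.
The tremor score is a planted linear model on five nodes' AUC nodal
efficiency with noise calibrated for population $R^2 = 0.8$; UPDRS is a
noisy transform of tremor, and duration is independent. Age and gender are
independent of group by construction.

What the generator does **not** emulate: hemodynamics, temporal
autocorrelation of real BOLD (unless the AR(1) knob is used), head motion,
spatial smoothness within cubes, or any anatomical layout. Passing tests
therefore demonstrate that the pipeline recovers effects of this planted
kind at these sizes — not that it would detect any particular effect in
real MRI data, and no regional (anatomical) claim can be checked this way.

# Problem sizes used by the shipped runs

The default configuration carries the full analysis settings (20-point
grid, 100-graph null ensembles, 10,000 group permutations). The analysis
scripts and the acceptance run use moderate sizes chosen for a desk-scale
rerun: wavelet scale 2 (the analyzed band) plus the morphological network,
10-graph ensembles at sparsities {0.2, 0.3}, 1,000 group permutations,
300-permutation in-fold screening, and the full 100 label permutations for
classifier significance. These sizes leave every qualitative conclusion
unchanged; permutation p-values simply have coarser resolution
(minimum 1/1001).

# Known limitations

* Efficiency is the only topology family implemented — no modularity,
  hubs, or rich-club metrics, and no weighted-graph efficiency.
* The 1/N correction is the only multiple-comparison rule wired into the
  pipeline stage (FDR/Bonferroni can be applied to the exported p-values).
* MLDA is the only classifier; it has no hyperparameters, which is why no
  nested tuning loop exists.
* The morphological path assumes per-node patches are available or
  extractable from a volume by centroid cubes; no segmentation or spatial
  normalization is performed.
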