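# conneff — multi-modal brain network efficiency analysis

`conneff` builds per-subject brain networks from two MRI modalities and
asks whether their topology separates patient groups, predicts clinical
scores, and agrees across modalities:

* **Functional networks**: Pearson correlations of maximal-overlap discrete
  wavelet transform (MODWT) detail coefficients of ROI time series, per
  wavelet scale (at TR = 2 s, scale 2 is the 0.0625–0.125 Hz band).
* **Morphological networks**: rotation-maximized Pearson similarity between
  small gray-matter cubes at the node locations (maximum over the cube's
  48 isometries).

Both are binarized over a sparsity grid (0.02–0.40, step 0.02) and
characterized by efficiency — for a binary graph `G` with `N` nodes and
shortest-path lengths `d_ij` (disconnected pairs contribute 0):

    E_glob(G) = 1/(N(N-1)) * sum_{i != j} 1/d_ij
    E_loc(G)  = 1/N * sum_i E_glob(G_i)       (G_i = neighbor subgraph of i)
    e_i       = 1/(N-1) * sum_{j != i} 1/d_ij

normalized against degree-preserving rewired null ensembles (small-world:
normalized E_loc > 1 with normalized E_glob ≈ 1) and summarized as
trapezoidal AUC across the grid. Downstream: Freedman–Lane permutation
group tests with age/gender covariates and a `p < 1/N` correction,
maximum-uncertainty LDA classification under leave-one-out
cross-validation with label-permutation significance, and
Pearson-screened least-squares regression linking nodal efficiency to
clinical scores and across modalities.

Everything runs end to end on a synthetic cohort generator (20 + 16
subjects, 264 nodes, 180 volumes at TR = 2 s) that plants a known
intra-module coupling gap between groups and a known linear clinical
model, so recovery is checkable. See the methods vignette
(`vignettes/network-efficiency-methods.Rmd`) for models, parameter
defaults, and design choices.

## Worked example

```r
library(conneff)

cfg <- run_config(
  cohort = cohort_config(seed = 11),
  scales = 2, analysis_scale = 2,
  n_null = 10, smallworld_sparsities = c(0.2, 0.3),
  n_perm_group = 1000, n_perm_screen = 300, n_perm_mvpa = 100,
  seed = 11)
run <- run_pipeline(cfg)
writeLines(make_report(run))
```

Representative output (seed 11, reduced permutation counts; a full run of
this configuration takes a few minutes on one core):

```
## Group differences (B - A, covariate-adjusted)
- fc_scale2: AUC E_glob diff +0.0141 (p = 0.000999); AUC E_loc diff -0.0309 (p = 0.000999); 42/264 nodes significant at p < 1/N
...
## Classification (LOOCV-MLDA on AUC nodal efficiency)
- fc_scale2: accuracy 0.94, sensitivity 0.94, specificity 0.95, z = 4.99 ...
...
## Planted-truth recovery
- noiseless clinical model: R^2 = 1.000000, coefficient signs recovered: TRUE
```

Reading it: the patients' AUC local efficiency is lower than the
controls' (the planted direction — their intra-module coupling was
weakened by 0.15), global efficiency is higher, the permutation p-values
are at their resolution floor (1/1001), dozens of nodes survive the 1/264
correction, the nodal-efficiency classifier separates the groups far above
its label-permutation null, and the noiseless regression recovers the
planted clinical coefficients exactly.

The same analysis is laid out as numbered steps under `analysis/`
(`01_simulate.R` → `06_regression.R`), each a thin driver over the package
that prints what it found and writes its tables under `results/`.

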