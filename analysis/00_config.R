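# Shared settings for the analysis scripts. Sourced by every numbered step.
#
# The cohort mirrors the study design: 20 controls + 16 patients, 264 nodes,
# 180 volumes at TR = 2 s (5 discarded), with the patient group's
# intra-module coupling weakened by 0.15. Analysis sizes are the moderate
# ones a desk-scale rerun uses: wavelet scale 2 plus the morphological
# network, 10-graph null ensembles at the mid-grid sparsities, 1000 group
# permutations, and 100 label permutations for classifier significance.

library(conneff)

ANALYSIS_SEED <- 20260922L
RESULTS_DIR <- file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(trailingOnly = FALSE), value = TRUE)[1])), "..", "results")
RESULTS_DIR <- normalizePath(RESULTS_DIR, mustWork = FALSE)
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

analysis_config <- function(seed = ANALYSIS_SEED) {
  run_config(
    cohort = cohort_config(seed = seed),
    scales = 2L, analysis_scale = 2L,
    n_null = 10L, smallworld_sparsities = c(0.2, 0.3),
    n_perm_group = 1000L, n_perm_screen = 300L, n_perm_mvpa = 100L,
    seed = seed)
}

res_path <- function(...) file.path(RESULTS_DIR, ...)
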