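#!/usr/bin/env Rscript
# Step 5 — MLDA classification of patients vs controls.
#
# AUC nodal efficiency patterns feed a permutation-screened
# maximum-uncertainty LDA under leave-one-out cross-validation; the
# observed accuracy is referred to a 100-label-permutation null.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(trailingOnly = FALSE), value = TRUE)[1])), "00_config.R"))

cfg <- analysis_config()
clinical <- read_cohort_table(res_path("cohort.tsv"))

for (modality in c("fc", "morpho")) {
  d <- read.delim(res_path(paste0("auc_nodal_", modality, ".tsv")),
                  check.names = FALSE)
  E <- as.matrix(d[, -1])
  ps <- permutation_significance(E, clinical$group,
                                 n_perm = cfg$n_perm_mvpa,
                                 p_thresh = cfg$screening_p,
                                 n_perm_screen = cfg$n_perm_screen,
                                 seed = cfg$seed + 50 +
                                   (modality == "morpho"))
  obs <- ps$observed
  cat(sprintf(
    "%s: accuracy %.2f, sensitivity %.2f, specificity %.2f, z = %.2f (null mean %.2f)\n",
    modality, obs$accuracy, obs$sensitivity, obs$specificity,
    ps$z_score, mean(ps$null_accuracy)))
  jsonlite::write_json(
    list(modality = modality, accuracy = obs$accuracy,
         sensitivity = obs$sensitivity, specificity = obs$specificity,
         z_score = ps$z_score, null_accuracy = ps$null_accuracy,
         selected_features = lapply(obs$selected, function(i) colnames(E)[i])),
    res_path(paste0("classifier_", modality, ".json")),
    auto_unbox = TRUE, digits = NA)
}
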