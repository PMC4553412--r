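#!/usr/bin/env Rscript
# Step 4 — clinical table and covariate-adjusted group inference.
#
# Clinical scores are generated from the planted linear model on functional
# AUC nodal efficiency (so later regression has a recoverable target), then
# the two groups are compared with Freedman-Lane permutation tests using
# age and gender as covariates, and nodal tests are corrected at p < 1/N.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(trailingOnly = FALSE), value = TRUE)[1])), "00_config.R"))

cfg <- analysis_config()
truth <- synthetic_truth(cfg$cohort)
read_auc <- function(modality) {
  d <- read.delim(res_path(paste0("auc_nodal_", modality, ".tsv")),
                  check.names = FALSE)
  m <- as.matrix(d[, -1]); rownames(m) <- d$subject_id; m
}
E_fc <- read_auc("fc")

clinical <- generate_clinical(truth, E_fc)
write_cohort_table(clinical, res_path("cohort.tsv"))
grp <- as.integer(clinical$group == "B")
covars <- clinical[, c("age", "gender")]

for (modality in c("fc", "morpho")) {
  gm <- read.delim(res_path(paste0("global_metrics_", modality, ".tsv")))
  for (metric in c("auc_e_glob", "auc_e_loc")) {
    v <- gm[[metric]]
    r <- permutation_test(v[grp == 0], v[grp == 1],
                          covariates = rbind(covars[grp == 0, , drop = FALSE],
                                             covars[grp == 1, , drop = FALSE]),
                          n_perm = cfg$n_perm_group,
                          seed = cfg$seed + match(metric, c("auc_e_glob", "auc_e_loc")),
                          metric = paste0(modality, "_", metric))
    cat(sprintf("%s %s: adjusted diff (B-A) %+0.4f, p = %.4g (%s)\n",
                modality, metric, r$observed_diff, r$p, r$direction))
  }
  E <- read_auc(modality)
  nodal <- permutation_test_matrix(E, grp, covars,
                                   n_perm = cfg$n_perm_group,
                                   seed = cfg$seed + 7)
  sig <- false_positive_correction(nodal$p, ncol(E))
  write.table(data.frame(node = colnames(E), diff = nodal$coef,
                         t = nodal$t_obs, p = nodal$p, significant = sig),
              res_path(paste0("nodal_stats_", modality, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s nodal: %d/%d nodes significant at p < 1/%d\n",
              modality, sum(sig), ncol(E), ncol(E)))
}

gm_fc <- read.delim(res_path("global_metrics_fc.tsv"))
pat <- grp == 1
pc <- partial_correlation(gm_fc$normalized_e_loc[pat], clinical$tremor[pat],
                          covars[pat, ])
cat(sprintf("patients: partial r(normalized E_loc, tremor) = %.3f, p = %.3g\n",
            pc$r, pc$p))
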