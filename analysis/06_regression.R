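#!/usr/bin/env Rscript
# Step 6 — screened regressions: clinical description and cross-modal links.
#
# Within patients, each clinical score is described from functional AUC
# nodal efficiency via Pearson screening (p < 0.01) plus least squares, and
# the two modalities are linked in both directions. The signed coefficients
# are exported for node-level visualization.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(trailingOnly = FALSE), value = TRUE)[1])), "00_config.R"))

cfg <- analysis_config()
clinical <- read_cohort_table(res_path("cohort.tsv"))
pat <- clinical$group == "B"
read_auc <- function(modality) {
  d <- read.delim(res_path(paste0("auc_nodal_", modality, ".tsv")),
                  check.names = FALSE)
  m <- as.matrix(d[, -1]); rownames(m) <- d$subject_id; m
}
E_fc <- read_auc("fc")[pat, ]
E_mo <- read_auc("morpho")[pat, ]
gm_fc <- read.delim(res_path("global_metrics_fc.tsv"))
gm_mo <- read.delim(res_path("global_metrics_morpho.tsv"))

report <- function(rr) {
  if (isTRUE(rr$no_model)) {
    cat(sprintf("%s: no predictor passed screening at p < %.2g\n",
                rr$response_id, cfg$screening_p))
    return(invisible(NULL))
  }
  cat(sprintf("%s: %d predictors, R^2 = %.3f, F p = %.3g\n",
              rr$response_id, length(rr$predictors), rr$r_squared,
              rr$f_p_value))
  coefs <- rr$coefficients[-1]
  write.table(data.frame(node = rr$predictors, coefficient = unname(coefs),
                         sign = sign(unname(coefs))),
              res_path(paste0("coefficients_", gsub("[^a-z_]", "_",
                                                    rr$response_id), ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

for (v in c("tremor", "updrs", "duration"))
  report(screened_mlrm(E_fc, clinical[[v]][pat], cfg$screening_p,
                       response_id = paste0(v, "~fc_nodal")))

report(cross_modal_link(gm_fc$auc_e_loc[pat], E_mo, cfg$screening_p,
                        response_id = "fc_e_loc~morpho_nodal"))
report(cross_modal_link(gm_mo$auc_e_loc[pat], E_fc, cfg$screening_p,
                        response_id = "morpho_e_loc~fc_nodal"))
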