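#!/usr/bin/env Rscript
# Step 1 — synthesize the cohort.
#
# Generates the two-group panel of ROI time series and the per-node
# gray-matter cubes, and records the planted ground truth. The patient
# group's intra-module coupling is weakened, so their local-efficiency
# curves should sit below the controls' downstream.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(trailingOnly = FALSE), value = TRUE)[1])), "00_config.R"))

cfg <- analysis_config()
truth <- synthetic_truth(cfg$cohort)
panel <- generate_timeseries(truth)
patches <- generate_gm_patches(truth)

write_panel(panel, res_path("panel_raw"))
write_patches(patches, res_path("patches"))
jsonlite::write_json(
  list(seed = cfg$cohort$seed,
       intra_module_r = cfg$cohort$intra_module_r,
       topology_gap = cfg$cohort$topology_gap,
       planted_clinical_weights = as.list(truth$planted_clinical_weights)),
  res_path("truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("cohort: %d controls + %d patients, %d nodes, %d timepoints\n",
            cfg$cohort$n_group_a, cfg$cohort$n_group_b,
            cfg$cohort$n_nodes, cfg$cohort$n_timepoints))
cat(sprintf("planted intra-module coupling: %.2f (controls) vs %.2f (patients)\n",
            cfg$cohort$intra_module_r,
            cfg$cohort$intra_module_r + cfg$cohort$topology_gap))
cat("wrote", res_path("panel_raw"), "and", res_path("patches"), "\n")
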