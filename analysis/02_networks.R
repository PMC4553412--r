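#!/usr/bin/env Rscript
# Step 2 — preprocess the time series and build both network modalities.
#
# Temporal preprocessing (discard 5 volumes, 0.01-0.1 Hz band-pass,
# detrend + nuisance regression), then per-subject functional connectivity
# from scale-2 MODWT wavelet correlations and morphological connectivity
# from rotation-maximized seed-cube similarities.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(trailingOnly = FALSE), value = TRUE)[1])), "00_config.R"))

cfg <- analysis_config()
panel <- read_panel(res_path("panel_raw"))
panel <- prep_panel(panel, n_discard = cfg$n_discard,
                    do_bandpass = cfg$do_bandpass,
                    f_lo = cfg$f_lo, f_hi = cfg$f_hi)
cat("preprocessing:", paste(attr(panel, "prep_log"), collapse = " -> "), "\n")

ws <- modwt_decompose(panel, wavelet = cfg$wavelet, J = cfg$J,
                      boundary = cfg$boundary)
band <- scale_band(cfg$analysis_scale, panel$tr_seconds)
cat(sprintf("scale %d isolates %.4f-%.4f Hz\n", cfg$analysis_scale,
            band[1], band[2]))
fc <- wavelet_correlation(ws, cfg$analysis_scale)

patches <- read_patches(res_path("patches"))
mo <- build_morpho_network(patches)
excl <- attr(mo, "exclusion_report")
cat(sprintf("morphological networks: %.4f%% of nodes excluded for zero variance\n",
            100 * excl$global_fraction))

dir.create(res_path("networks"), showWarnings = FALSE)
for (id in names(fc))
  write_connectivity(fc[[id]], res_path("networks", paste0("fc_", id, ".tsv")))
for (id in names(mo))
  write_connectivity(mo[[id]], res_path("networks", paste0("morpho_", id, ".tsv")))
cat("wrote", length(fc) + length(mo), "connectivity matrices to",
    res_path("networks"), "\n")
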