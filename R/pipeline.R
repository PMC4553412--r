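#' Assemble and validate a pipeline run configuration
#'
#' Consolidates every tunable of the end-to-end analysis. Defaults follow
#' the study design: sparsity grid 0.02-0.40 in steps of 0.02, 100-graph
#' null ensembles, 10,000 group permutations, 100 label permutations for
#' classifier significance, and screening at p < 0.01. Permutation and null
#' counts can be reduced for quick runs; every stochastic stage draws its
#' seed deterministically from `seed`.
#'
#' @param cohort A [cohort_config()] (default: the standard synthetic
#'   design).
#' @param n_discard Initial volumes to discard (default 5).
#' @param do_bandpass Apply the 0.01-0.1 Hz band-pass (default TRUE).
#' @param f_lo,f_hi Band-pass edges in Hz.
#' @param wavelet,J,boundary MODWT settings (defaults `"la8"`, 4,
#'   `"periodic"`).
#' @param scales Wavelet scales to analyze (default 1:4).
#' @param analysis_scale Scale used for clinical generation, classification,
#'   and regression (default 2).
#' @param sparsity_lo,sparsity_hi,sparsity_step Sparsity grid.
#' @param n_null Null-ensemble size per graph (default 100).
#' @param smallworld_sparsities Sparsities at which normalized efficiencies
#'   are evaluated (default 0.20, 0.25, 0.30: a mid-grid band chosen so that
#'   modular networks are above their percolation density — a graph with m
#'   equal modules has only about 1/m of its node pairs within modules, so
#'   below that sparsity the strongest edges cannot connect the graph and
#'   normalized global efficiency is not interpretable).
#' @param n_perm_group Group-test permutations (default 10000).
#' @param n_perm_screen Screening permutations (default 1000).
#' @param n_perm_mvpa Label permutations for classifier significance
#'   (default 100).
#' @param screening_p Screening threshold for feature selection and
#'   regression (default 0.01).
#' @param smallworld_tol Tolerance of the "normalized global efficiency
#'   approximately 1" criterion (default 0.1).
#' @param classify Run the MLDA classification stage (default TRUE).
#' @param regress Run the regression stage (default TRUE).
#' @param out_dir Optional output directory; when given, stage outputs and a
#'   run manifest are written there.
#' @param seed Master seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       n_discard = 5L, do_bandpass = TRUE,
                       f_lo = 0.01, f_hi = 0.1,
                       wavelet = "la8", J = 4L, boundary = "periodic",
                       scales = 1:4, analysis_scale = 2L,
                       sparsity_lo = 0.02, sparsity_hi = 0.40,
                       sparsity_step = 0.02,
                       n_null = 100L,
                       smallworld_sparsities = c(0.20, 0.25, 0.30),
                       n_perm_group = 10000L, n_perm_screen = 1000L,
                       n_perm_mvpa = 100L, screening_p = 0.01,
                       smallworld_tol = 0.1,
                       classify = TRUE, regress = TRUE,
                       out_dir = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  if (sparsity_step <= 0) stop("sparsity_step must be > 0")
  grid <- sparsity_grid(sparsity_lo, sparsity_hi, sparsity_step)
  if (is.null(smallworld_sparsities)) smallworld_sparsities <- grid
  if (!all(smallworld_sparsities > 0 & smallworld_sparsities < 1))
    stop("smallworld_sparsities must lie in (0, 1)")
  stopifnot(analysis_scale %in% scales, J >= max(scales),
            n_null >= 1, n_perm_group >= 1, n_perm_mvpa >= 20,
            screening_p > 0, screening_p <= 1)
  structure(list(cohort = cohort, n_discard = as.integer(n_discard),
                 do_bandpass = do_bandpass, f_lo = f_lo, f_hi = f_hi,
                 wavelet = wavelet, J = as.integer(J), boundary = boundary,
                 scales = as.integer(scales),
                 analysis_scale = as.integer(analysis_scale),
                 sparsity_grid = grid,
                 n_null = as.integer(n_null),
                 smallworld_sparsities = smallworld_sparsities,
                 n_perm_group = as.integer(n_perm_group),
                 n_perm_screen = as.integer(n_perm_screen),
                 n_perm_mvpa = as.integer(n_perm_mvpa),
                 screening_p = screening_p,
                 smallworld_tol = smallworld_tol,
                 classify = classify, regress = regress,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Scalar keys map directly onto [run_config()] arguments; keys under
#' `cohort:` map onto [cohort_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  y$cohort <- do.call(cohort_config, cohort_args)
  do.call(run_config, y)
}

stage_msg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[conneff] %s", sprintf(fmt, ...)))
}

# AUC efficiency summaries for a list of connectivity matrices.
profile_modality <- function(nets, grid) {
  n <- length(nets)
  auc_glob <- numeric(n)
  auc_loc <- numeric(n)
  auc_nodal <- NULL
  curves_loc <- matrix(NA_real_, n, length(grid))
  curves_glob <- matrix(NA_real_, n, length(grid))
  for (s in seq_len(n)) {
    pr <- efficiency_profile(nets[[s]], grid)
    auc_glob[s] <- pr$auc_e_glob
    auc_loc[s] <- pr$auc_e_loc
    if (is.null(auc_nodal))
      auc_nodal <- matrix(NA_real_, n, length(pr$auc_nodal),
                          dimnames = list(names(nets), names(pr$auc_nodal)))
    auc_nodal[s, ] <- pr$auc_nodal
    curves_loc[s, ] <- pr$e_loc
    curves_glob[s, ] <- pr$e_glob
  }
  names(auc_glob) <- names(auc_loc) <- names(nets)
  rownames(curves_loc) <- rownames(curves_glob) <- names(nets)
  list(auc_e_glob = auc_glob, auc_e_loc = auc_loc, auc_nodal = auc_nodal,
       e_loc_curves = curves_loc, e_glob_curves = curves_glob,
       sparsity_grid = grid)
}

# Normalized efficiencies averaged over the requested sparsities.
smallworld_modality <- function(nets, sparsities, n_null, tol, seed) {
  n <- length(nets)
  ng <- matrix(NA_real_, n, length(sparsities))
  nl <- matrix(NA_real_, n, length(sparsities))
  for (s in seq_len(n)) {
    for (k in seq_along(sparsities)) {
      G <- threshold_by_sparsity(nets[[s]], sparsities[k])
      ens <- null_ensemble(G, n_null = n_null,
                           seed = derive_seed(seed, sprintf("nulls%d_%d", s, k)))
      nz <- normalize_against_null(global_efficiency(G), local_efficiency(G), ens)
      ng[s, k] <- nz$normalized_e_glob
      nl[s, k] <- nz$normalized_e_loc
    }
  }
  mg <- rowMeans(ng)
  ml <- rowMeans(nl)
  flags <- mapply(is_small_world, ml, mg, MoreArgs = list(tol = tol))
  list(normalized_e_glob = mg, normalized_e_loc = ml, small_world = flags,
       per_sparsity_glob = ng, per_sparsity_loc = nl, sparsities = sparsities)
}

#' Run the full multi-modal network analysis pipeline
#'
#' Stages, in dependency order: synthesize cohort -> temporal preprocessing
#' -> MODWT functional networks (all configured scales) -> morphological
#' networks -> efficiency profiles and AUCs over the sparsity grid ->
#' small-world assessment against degree-preserving nulls -> clinical table
#' generation from nodal efficiency -> covariate-adjusted permutation group
#' inference with 1/N correction -> MLDA classification with LOOCV and
#' label-permutation significance -> screened regressions (clinical and
#' cross-modal). Identical configurations (including seed) reproduce all
#' outputs exactly.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage progress messages (default TRUE).
#' @return A `conneff_run` list with elements `truth`, `panel`, `networks`,
#'   `profiles`, `smallworld`, `clinical`, `group_stats`, `classification`,
#'   `regressions`, `truth_recovery`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t_start <- proc.time()[3]
  cfg <- config$cohort
  timings <- c()
  tick <- function(name) {
    timings[name] <<- round(proc.time()[3] - t_start, 2)
  }

  stage_msg(quiet, "synth: %d+%d subjects, %d nodes, %d timepoints",
            cfg$n_group_a, cfg$n_group_b, cfg$n_nodes, cfg$n_timepoints)
  truth <- synthetic_truth(cfg)
  panel_raw <- generate_timeseries(truth)
  patches <- generate_gm_patches(truth)
  tick("synth")

  panel <- prep_panel(panel_raw, n_discard = config$n_discard,
                      do_bandpass = config$do_bandpass,
                      f_lo = config$f_lo, f_hi = config$f_hi)
  tick("prep")

  stage_msg(quiet, "fc: MODWT %s J=%d, scales %s", config$wavelet, config$J,
            paste(config$scales, collapse = ","))
  ws <- modwt_decompose(panel, wavelet = config$wavelet, J = config$J,
                        boundary = config$boundary)
  networks <- list()
  for (j in config$scales)
    networks[[paste0("fc_scale", j)]] <- wavelet_correlation(ws, j)
  networks$morpho <- build_morpho_network(patches)
  tick("networks")

  stage_msg(quiet, "metrics: %d sparsities x %d networks",
            length(config$sparsity_grid), length(networks))
  profiles <- lapply(networks, profile_modality, grid = config$sparsity_grid)
  tick("metrics")

  stage_msg(quiet, "smallworld: %d sparsities, %d nulls",
            length(config$smallworld_sparsities), config$n_null)
  sw_modalities <- c(paste0("fc_scale", config$analysis_scale), "morpho")
  smallworld <- lapply(sw_modalities, function(m)
    smallworld_modality(networks[[m]], config$smallworld_sparsities,
                        config$n_null, config$smallworld_tol,
                        derive_seed(config$seed, paste0("sw_", m))))
  names(smallworld) <- sw_modalities
  tick("smallworld")

  fc_key <- paste0("fc_scale", config$analysis_scale)
  clinical <- generate_clinical(truth, profiles[[fc_key]]$auc_nodal)
  covars <- clinical[, c("age", "gender")]
  group <- as.integer(clinical$group == "B")
  tick("clinical")

  stage_msg(quiet, "stats: %d permutations", config$n_perm_group)
  group_stats <- lapply(names(profiles), function(m) {
    pr <- profiles[[m]]
    glob <- permutation_test(pr$auc_e_glob[group == 0], pr$auc_e_glob[group == 1],
                             covariates = rbind(covars[group == 0, ],
                                                covars[group == 1, ]),
                             n_perm = config$n_perm_group,
                             seed = derive_seed(config$seed, paste0("pg_", m)),
                             metric = paste0(m, "_auc_e_glob"))
    loc <- permutation_test(pr$auc_e_loc[group == 0], pr$auc_e_loc[group == 1],
                            covariates = rbind(covars[group == 0, ],
                                               covars[group == 1, ]),
                            n_perm = config$n_perm_group,
                            seed = derive_seed(config$seed, paste0("pl_", m)),
                            metric = paste0(m, "_auc_e_loc"))
    nodal <- permutation_test_matrix(pr$auc_nodal, group, covars,
                                     n_perm = config$n_perm_group,
                                     seed = derive_seed(config$seed,
                                                        paste0("pn_", m)))
    nodal_sig <- false_positive_correction(nodal$p, ncol(pr$auc_nodal))
    list(e_glob = glob, e_loc = loc,
         nodal = data.frame(node = colnames(pr$auc_nodal),
                            diff = nodal$coef, t = nodal$t_obs, p = nodal$p,
                            significant = nodal_sig))
  })
  names(group_stats) <- names(profiles)

  # Normalized local efficiency vs tremor within patients, age/gender adjusted
  pat <- group == 1
  tremor_cor <- tryCatch(
    partial_correlation(smallworld[[fc_key]]$normalized_e_loc[pat],
                        clinical$tremor[pat], covars[pat, ]),
    error = function(e) NULL)
  tick("stats")

  classification <- NULL
  if (config$classify) {
    stage_msg(quiet, "classify: LOOCV-MLDA, %d label permutations",
              config$n_perm_mvpa)
    classification <- lapply(sw_modalities, function(m)
      permutation_significance(profiles[[m]]$auc_nodal, clinical$group,
                               n_perm = config$n_perm_mvpa,
                               p_thresh = config$screening_p,
                               n_perm_screen = config$n_perm_screen,
                               seed = derive_seed(config$seed, paste0("cl_", m))))
    names(classification) <- sw_modalities
  }
  tick("classify")

  regressions <- NULL
  if (config$regress) {
    stage_msg(quiet, "regress: screened MLRM")
    E_fc <- profiles[[fc_key]]$auc_nodal[pat, , drop = FALSE]
    E_mo <- profiles$morpho$auc_nodal[pat, , drop = FALSE]
    clin <- lapply(c("tremor", "updrs", "duration"), function(v)
      screened_mlrm(E_fc, clinical[[v]][pat], config$screening_p,
                    response_id = paste0(v, "~fc_nodal")))
    names(clin) <- c("tremor", "updrs", "duration")
    cross <- list(
      fc_from_morpho = cross_modal_link(profiles[[fc_key]]$auc_e_loc[pat],
                                        E_mo, config$screening_p,
                                        "fc_e_loc~morpho_nodal"),
      morpho_from_fc = cross_modal_link(profiles$morpho$auc_e_loc[pat],
                                        E_fc, config$screening_p,
                                        "morpho_e_loc~fc_nodal"))
    regressions <- list(clinical = clin, cross_modal = cross)
  }
  tick("regress")

  # Planted-truth recovery: noiseless clinical model on the true predictors
  beta <- truth$planted_clinical_weights
  E_true <- profiles[[fc_key]]$auc_nodal[, names(beta), drop = FALSE]
  linpred <- attr(clinical, "planted_linpred")
  # exact fit by construction; summary.lm's perfect-fit warning is expected
  noiseless_fit <- suppressWarnings(
    fit_mlrm(E_true, linpred, response_id = "noiseless_tremor"))
  truth_recovery <- list(
    noiseless_r_squared = noiseless_fit$r_squared,
    noiseless_signs_match = all(sign(coef(noiseless_fit$fit)[-1]) ==
                                  sign(beta)),
    planted_beta = beta,
    recovered_beta = coef(noiseless_fit$fit)[-1])

  manifest <- list(
    package_version = as.character(utils::packageVersion("conneff")),
    seed = config$seed,
    n_subjects = cfg$n_group_a + cfg$n_group_b,
    n_nodes = cfg$n_nodes,
    scales = config$scales,
    sparsity_grid = config$sparsity_grid,
    n_null = config$n_null,
    n_perm_group = config$n_perm_group,
    n_perm_mvpa = config$n_perm_mvpa,
    timings_seconds = as.list(timings))

  run <- structure(list(config = config, truth = truth, panel = panel,
                        networks = networks, profiles = profiles,
                        smallworld = smallworld, clinical = clinical,
                        group_stats = group_stats, tremor_cor = tremor_cor,
                        classification = classification,
                        regressions = regressions,
                        truth_recovery = truth_recovery,
                        manifest = manifest),
                   class = "conneff_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

# Persist the main tables and the manifest of a run.
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_table(run$clinical, file.path(dir, "cohort.tsv"))
  for (m in names(run$profiles)) {
    pr <- run$profiles[[m]]
    write.table(
      data.frame(subject_id = names(pr$auc_e_glob),
                 auc_e_glob = pr$auc_e_glob, auc_e_loc = pr$auc_e_loc),
      file.path(dir, paste0("auc_global_", m, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cbind(subject_id = rownames(pr$auc_nodal),
                      as.data.frame(pr$auc_nodal)),
                file.path(dir, paste0("auc_nodal_", m, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(run$group_stats[[m]]$nodal,
                file.path(dir, paste0("nodal_stats_", m, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Human-readable summary of a pipeline run
#'
#' Collates small-world flags, group-difference tests with corrected
#' significance, classifier reports with z-scores, regression reports, and
#' the planted-truth recovery comparison into one text document. Sections
#' whose stage was not run are omitted cleanly.
#'
#' @param run A `conneff_run` from [run_pipeline()].
#' @param path Optional file to write the report to.
#' @return Character vector of report lines, invisibly when `path` is given.
#' @export
make_report <- function(run, path = NULL) {
  stopifnot(inherits(run, "conneff_run"))
  L <- c("# Multi-modal network efficiency run report", "")
  grp <- as.integer(run$clinical$group == "B")
  L <- c(L, sprintf("Subjects: %d controls (A) + %d patients (B); %d nodes; seed %d",
                    sum(grp == 0), sum(grp == 1),
                    run$manifest$n_nodes, run$manifest$seed), "")
  L <- c(L, "## Small-world assessment")
  for (m in names(run$smallworld)) {
    sw <- run$smallworld[[m]]
    for (g in c(0, 1)) {
      sel <- grp == g
      L <- c(L, sprintf(
        "- %s group %s: mean normalized E_loc %.3f, E_glob %.3f, small-world in %d/%d subjects",
        m, c("A", "B")[g + 1], mean(sw$normalized_e_loc[sel]),
        mean(sw$normalized_e_glob[sel]), sum(sw$small_world[sel]), sum(sel)))
    }
  }
  L <- c(L, "", "## Group differences (B - A, covariate-adjusted)")
  for (m in names(run$group_stats)) {
    gs <- run$group_stats[[m]]
    L <- c(L, sprintf("- %s: AUC E_glob diff %+0.4f (p = %.4g); AUC E_loc diff %+0.4f (p = %.4g); %d/%d nodes significant at p < 1/N",
                      m, gs$e_glob$observed_diff, gs$e_glob$p,
                      gs$e_loc$observed_diff, gs$e_loc$p,
                      sum(gs$nodal$significant), nrow(gs$nodal)))
  }
  if (!is.null(run$tremor_cor))
    L <- c(L, "", sprintf(
      "Partial correlation (patients), normalized E_loc vs tremor: r = %.3f, p = %.4g",
      run$tremor_cor$r, run$tremor_cor$p))
  if (!is.null(run$classification)) {
    L <- c(L, "", "## Classification (LOOCV-MLDA on AUC nodal efficiency)")
    for (m in names(run$classification)) {
      cl <- run$classification[[m]]
      L <- c(L, sprintf(
        "- %s: accuracy %.2f, sensitivity %.2f, specificity %.2f, z = %.2f vs %d-permutation null",
        m, cl$observed$accuracy, cl$observed$sensitivity,
        cl$observed$specificity, cl$z_score, length(cl$null_accuracy)))
    }
  }
  if (!is.null(run$regressions)) {
    L <- c(L, "", "## Screened regressions (patients)")
    for (v in names(run$regressions$clinical)) {
      rr <- run$regressions$clinical[[v]]
      L <- c(L, if (isTRUE(rr$no_model))
        sprintf("- %s: no predictor passed screening", v)
        else sprintf("- %s: %d predictors, R^2 = %.3f (F p = %.4g)",
                     v, length(rr$predictors), rr$r_squared, rr$f_p_value))
    }
    for (v in names(run$regressions$cross_modal)) {
      rr <- run$regressions$cross_modal[[v]]
      L <- c(L, if (isTRUE(rr$no_model))
        sprintf("- %s: no predictor passed screening", v)
        else sprintf("- %s: %d predictors, R^2 = %.3f (F p = %.4g)",
                     v, length(rr$predictors), rr$r_squared, rr$f_p_value))
    }
  }
  L <- c(L, "", "## Planted-truth recovery",
         sprintf("- noiseless clinical model: R^2 = %.6f, coefficient signs recovered: %s",
                 run$truth_recovery$noiseless_r_squared,
                 run$truth_recovery$noiseless_signs_match))
  if (!is.null(path)) {
    writeLines(L, path)
    return(invisible(L))
  }
  L
}
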