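#' Configuration for a synthetic two-group cohort
#'
#' Defines the study design emulated by the synthetic generator: a two-group
#' cohort (controls vs patients) with modular resting-state connectivity,
#' per-node gray-matter cubes, and clinical scores linearly tied to nodal
#' efficiency. Defaults mirror a 20 + 16 subject design with 264 network
#' nodes and 180 acquired volumes at TR = 2 s (175 retained after the
#' initial-volume discard), with a group difference planted as a shift in
#' intra-module coupling.
#'
#' @param n_group_a Number of subjects in group A (controls). Default 20.
#' @param n_group_b Number of subjects in group B (patients). Default 16.
#' @param n_nodes Number of network nodes (ROIs). Default 264.
#' @param n_timepoints Number of acquired volumes per subject. Default 180.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param n_modules Number of connectivity modules; must divide `n_nodes`.
#' @param intra_module_r Within-module correlation for group A, in \[0, 1).
#' @param inter_module_r Between-module correlation, in \[0, 1); must be
#'   strictly below `intra_module_r`.
#' @param topology_gap Shift added to group B's intra-module correlation.
#'   Negative values weaken patient within-module coupling, lowering their
#'   local-efficiency curves. Default -0.15.
#' @param cube_edge Odd edge length (voxels) of gray-matter cubes. Default 3.
#' @param clinical_beta Named numeric vector of planted regression weights on
#'   AUC nodal efficiency (names are node ids); drives the tremor score.
#' @param clinical_noise_sd Standard deviation of clinical score noise, or
#'   `NULL` to derive it at generation time for a population R-squared of
#'   `clinical_r2`.
#' @param clinical_r2 Target population R-squared of the planted clinical
#'   model when `clinical_noise_sd` is `NULL`. Default 0.8.
#' @param zero_var_fraction Fraction of nodes given zero-variance gray-matter
#'   cubes (exercises the exclusion rule). Default 1e-4 (0.01%).
#' @param gm_noise_sd Subject-level noise added to gray-matter archetypes.
#' @param ar1 Optional AR(1) coefficient for temporal autocorrelation of the
#'   generated series (0 = white noise, the default).
#' @param seed Integer master seed.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_group_a = 20L, n_group_b = 16L, n_nodes = 264L,
                          n_timepoints = 180L, tr_seconds = 2,
                          n_modules = 8L, intra_module_r = 0.5,
                          inter_module_r = 0.1, topology_gap = -0.15,
                          cube_edge = 3L,
                          clinical_beta = NULL,
                          clinical_noise_sd = NULL, clinical_r2 = 0.8,
                          zero_var_fraction = 1e-4, gm_noise_sd = 0.5,
                          ar1 = 0, seed = 1L) {
  stopifnot(n_group_a >= 2, n_group_b >= 2, n_nodes >= 2,
            n_timepoints >= 2, tr_seconds > 0, n_modules >= 1)
  if (n_nodes %% n_modules != 0)
    stop("n_nodes must be divisible by n_modules")
  if (!(inter_module_r >= 0 && inter_module_r < intra_module_r &&
        intra_module_r < 1))
    stop("require 0 <= inter_module_r < intra_module_r < 1")
  intra_b <- intra_module_r + topology_gap
  if (intra_b <= inter_module_r || intra_b >= 1)
    stop("topology_gap pushes group B intra-module coupling outside (inter_module_r, 1)")
  if (cube_edge %% 2 != 1 || cube_edge < 3)
    stop("cube_edge must be odd and >= 3")
  if (is.null(clinical_beta)) {
    k <- min(5L, n_nodes)
    clinical_beta <- stats::setNames(c(8, -6, 5, -4, 3)[seq_len(k)],
                                     node_ids(n_nodes)[seq_len(k)])
  }
  if (is.null(names(clinical_beta)) || anyNA(names(clinical_beta)))
    stop("clinical_beta must be a named vector (names = node ids)")
  structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_nodes = as.integer(n_nodes), n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, n_modules = as.integer(n_modules),
    intra_module_r = intra_module_r, inter_module_r = inter_module_r,
    topology_gap = topology_gap, cube_edge = as.integer(cube_edge),
    clinical_beta = clinical_beta, clinical_noise_sd = clinical_noise_sd,
    clinical_r2 = clinical_r2, zero_var_fraction = zero_var_fraction,
    gm_noise_sd = gm_noise_sd, ar1 = ar1, seed = as.integer(seed)
  ), class = "cohort_config")
}

node_ids <- function(n) sprintf("n%03d", seq_len(n))

#' Block-constant correlation matrix with modular structure
#'
#' Builds the group-level target correlation matrix: unit diagonal,
#' `intra_r` within each of `n_modules` equal-sized contiguous blocks,
#' `inter_r` between blocks. The result is repaired to positive
#' semidefiniteness by clipping negative eigenvalues at zero (block-constant
#' matrices with `0 <= inter_r < intra_r < 1` are already PSD, so the repair
#' is a guard, not the common path).
#'
#' @param n_nodes Number of nodes; must be divisible by `n_modules`.
#' @param n_modules Number of modules.
#' @param intra_r Within-module correlation, in \[0, 1).
#' @param inter_r Between-module correlation, in \[0, `intra_r`).
#' @return A symmetric `n_nodes` x `n_nodes` PSD matrix with unit diagonal.
#' @export
plant_block_covariance <- function(n_nodes, n_modules, intra_r, inter_r = 0) {
  stopifnot(n_nodes %% n_modules == 0)
  if (!(inter_r >= 0 && inter_r <= intra_r && intra_r < 1))
    stop("require 0 <= inter_r <= intra_r < 1")
  module <- rep(seq_len(n_modules), each = n_nodes / n_modules)
  S <- matrix(inter_r, n_nodes, n_nodes)
  same <- outer(module, module, "==")
  S[same] <- intra_r
  diag(S) <- 1
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    lam <- pmax(ev$values, 0)
    S <- ev$vectors %*% (lam * t(ev$vectors))
    S <- (S + t(S)) / 2
    d <- sqrt(diag(S))
    S <- S / outer(d, d)
    diag(S) <- 1
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("block covariance not PSD after eigenvalue clipping; ",
           "reject parameters intra_r=", intra_r, " inter_r=", inter_r)
  }
  dimnames(S) <- list(node_ids(n_nodes), node_ids(n_nodes))
  S
}

#' Planted ground truth for a synthetic cohort
#'
#' Assembles the target group covariances and planted clinical weights that
#' downstream recovery is judged against.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  Sa <- plant_block_covariance(config$n_nodes, config$n_modules,
                               config$intra_module_r, config$inter_module_r)
  Sb <- plant_block_covariance(config$n_nodes, config$n_modules,
                               config$intra_module_r + config$topology_gap,
                               config$inter_module_r)
  structure(list(target_covariance_a = Sa, target_covariance_b = Sb,
                 planted_clinical_weights = config$clinical_beta,
                 config = config, seed = config$seed),
            class = "synthetic_truth")
}

# Symmetric PSD square root via eigendecomposition (Cholesky would fail on
# the PSD-but-singular boundary).
matrix_sqrt <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  ev$vectors %*% (sqrt(lam) * t(ev$vectors))
}

#' Generate a panel of ROI time series
#'
#' Each subject's series is zero-mean Gaussian noise colored by the symmetric
#' square root of that subject's group covariance; optionally an AR(1) filter
#' adds temporal autocorrelation before coloring (cross-correlations are
#' unaffected). Group A subjects come first in the panel.
#'
#' @param truth A [synthetic_truth()].
#' @param n_timepoints Number of timepoints; defaults to the config value.
#' @param seed Integer seed; defaults to the config seed.
#' @return A `roi_panel`: list with `subjects` (named list of
#'   timepoints x nodes matrices), `subject_ids`, `group` (factor "A"/"B"),
#'   `node_ids`, `tr_seconds`.
#' @export
generate_timeseries <- function(truth, n_timepoints = NULL, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  if (is.null(n_timepoints)) n_timepoints <- cfg$n_timepoints
  if (is.null(seed)) seed <- derive_seed(cfg$seed, "cohort")
  set.seed(seed)
  n <- cfg$n_group_a + cfg$n_group_b
  group <- factor(rep(c("A", "B"), c(cfg$n_group_a, cfg$n_group_b)))
  ids <- sprintf("sub%02d", seq_len(n))
  Ma <- matrix_sqrt(truth$target_covariance_a)
  Mb <- matrix_sqrt(truth$target_covariance_b)
  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    Z <- matrix(rnorm(n_timepoints * cfg$n_nodes), n_timepoints, cfg$n_nodes)
    if (cfg$ar1 != 0) {
      phi <- cfg$ar1
      Z <- apply(Z, 2, function(z)
        as.numeric(stats::filter(z * sqrt(1 - phi^2), phi,
                                 method = "recursive")))
    }
    X <- Z %*% (if (group[s] == "A") t(Ma) else t(Mb))
    colnames(X) <- node_ids(cfg$n_nodes)
    subjects[[s]] <- X
  }
  names(subjects) <- ids
  structure(list(subjects = subjects, subject_ids = ids, group = group,
                 node_ids = node_ids(cfg$n_nodes),
                 tr_seconds = cfg$tr_seconds),
            class = "roi_panel")
}

#' Generate per-node gray-matter cube patches
#'
#' Each module of nodes shares a random archetype pattern; a node's cube for
#' a given subject is its module archetype plus subject-specific Gaussian
#' noise, shifted to non-negative values. A configurable fraction of nodes
#' (the same nodes for every subject) receive constant cubes to exercise the
#' zero-variance exclusion rule of morphological network construction.
#'
#' @param truth A [synthetic_truth()].
#' @param cube_edge Odd cube edge length; defaults to the config value.
#' @param seed Integer seed; defaults to a stage seed derived from the config.
#' @return A `gm_patch_set`: list with `patches` (named list, one
#'   `cube_edge^3` x nodes matrix per subject, columns = flattened cubes),
#'   `cube_edge`, `node_ids`, `subject_ids`, `group`, `zero_variance_nodes`.
#' @export
generate_gm_patches <- function(truth, cube_edge = NULL, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  if (is.null(cube_edge)) cube_edge <- cfg$cube_edge
  stopifnot(cube_edge %% 2 == 1, cube_edge >= 3)
  if (is.null(seed)) seed <- derive_seed(cfg$seed, "morph")
  set.seed(seed)
  n <- cfg$n_group_a + cfg$n_group_b
  nv <- cube_edge^3
  module <- rep(seq_len(cfg$n_modules), each = cfg$n_nodes / cfg$n_modules)
  archetypes <- matrix(rnorm(nv * cfg$n_modules), nv, cfg$n_modules)
  n_zero <- round(cfg$zero_var_fraction * cfg$n_nodes)
  zero_nodes <- if (n_zero > 0) sample.int(cfg$n_nodes, n_zero) else integer(0)
  ids <- sprintf("sub%02d", seq_len(n))
  group <- factor(rep(c("A", "B"), c(cfg$n_group_a, cfg$n_group_b)))
  patches <- vector("list", n)
  for (s in seq_len(n)) {
    P <- archetypes[, module, drop = FALSE] +
      matrix(rnorm(nv * cfg$n_nodes, sd = cfg$gm_noise_sd), nv, cfg$n_nodes)
    P <- P - min(P)  # gray-matter values are non-negative
    if (length(zero_nodes)) P[, zero_nodes] <- 0.5
    colnames(P) <- node_ids(cfg$n_nodes)
    patches[[s]] <- P
  }
  names(patches) <- ids
  structure(list(patches = patches, cube_edge = as.integer(cube_edge),
                 node_ids = node_ids(cfg$n_nodes), subject_ids = ids,
                 group = group,
                 zero_variance_nodes = node_ids(cfg$n_nodes)[zero_nodes]),
            class = "gm_patch_set")
}

#' Generate a clinical table tied to nodal efficiency
#'
#' The tremor score is a planted linear model on AUC nodal efficiency:
#' `score_s = sum_i beta_i e_i(s) + eps`, `eps ~ N(0, noise_sd)`. UPDRS is a
#' noisy monotone transform of the tremor score and duration is independent,
#' so only tremor carries the planted signal. Age and gender are generated
#' independently of group.
#'
#' @param truth A [synthetic_truth()].
#' @param nodal_efficiency Subjects x nodes matrix of (AUC) nodal efficiency,
#'   with node ids as column names and subject ids as row names.
#' @param beta Named planted weights; defaults to the config's
#'   `clinical_beta`.
#' @param noise_sd Noise standard deviation; `NULL` derives it from the
#'   config's `clinical_r2` target against the realized linear predictor.
#' @param seed Integer seed; defaults to a stage seed.
#' @return A data.frame with columns subject_id, group, age, gender, tremor,
#'   updrs, duration, plus attribute `"noise_sd"` (the value used).
#' @export
generate_clinical <- function(truth, nodal_efficiency, beta = NULL,
                              noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  if (is.null(beta)) beta <- truth$planted_clinical_weights
  if (is.null(seed)) seed <- derive_seed(cfg$seed, "stats")
  stopifnot(all(names(beta) %in% colnames(nodal_efficiency)))
  set.seed(seed)
  n <- nrow(nodal_efficiency)
  linpred <- as.numeric(nodal_efficiency[, names(beta), drop = FALSE] %*% beta)
  if (is.null(noise_sd)) noise_sd <- cfg$clinical_noise_sd
  if (is.null(noise_sd)) {
    r2 <- cfg$clinical_r2
    noise_sd <- if (sd(linpred) == 0) 1 else sd(linpred) * sqrt((1 - r2) / r2)
  }
  tremor <- linpred + rnorm(n, sd = noise_sd)
  updrs <- 27 + 10 * as.numeric(scale(tremor)) + rnorm(n, sd = 5)
  duration <- runif(n, 0.5, 6)
  stopifnot(n == cfg$n_group_a + cfg$n_group_b)
  group <- factor(rep(c("A", "B"), c(cfg$n_group_a, cfg$n_group_b)))
  structure(data.frame(
    subject_id = rownames(nodal_efficiency) %||% sprintf("sub%02d", seq_len(n)),
    group = group,
    age = round(rnorm(n, 60, 10)),
    gender = factor(ifelse(rbinom(n, 1, 0.5) == 1, "M", "F"),
                    levels = c("F", "M")),
    tremor = tremor, updrs = updrs, duration = duration,
    stringsAsFactors = FALSE
  ), noise_sd = noise_sd, planted_linpred = linpred)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
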