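#' Binary graph container
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @return Object of class `binary_graph` with fields `adjacency`,
#'   `n_nodes`, `n_edges`.
#' @export
binary_graph <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  A <- matrix(as.integer(adjacency != 0), nrow(adjacency))
  dimnames(A) <- dimnames(adjacency)
  if (any(A != t(A))) stop("adjacency must be symmetric")
  diag(A) <- 0L
  structure(list(adjacency = A, n_nodes = nrow(A),
                 n_edges = sum(A) %/% 2L),
            class = "binary_graph")
}

as_adjacency <- function(G) {
  if (inherits(G, "binary_graph")) G$adjacency
  else binary_graph(G)$adjacency
}

#' The standard sparsity grid
#'
#' @param lo,hi,step Grid limits and spacing (defaults 0.02, 0.40, 0.02,
#'   giving 20 thresholds).
#' @return Numeric vector of sparsity values.
#' @export
sparsity_grid <- function(lo = 0.02, hi = 0.40, step = 0.02) {
  stopifnot(step > 0, lo > 0, hi < 1, lo <= hi)
  seq(lo, hi + 1e-12, by = step)
}

#' Binarize a connectivity matrix at a target sparsity
#'
#' Keeps the `round(s * N * (N - 1) / 2)` largest off-diagonal weights as
#' edges. Missing weights are never selected; ties at the cut are broken
#' deterministically by (weight descending, row index, column index).
#'
#' @param cm A `connectivity_matrix` or a symmetric weight matrix.
#' @param s Target sparsity in (0, 1).
#' @return A `binary_graph`.
#' @export
threshold_by_sparsity <- function(cm, s) {
  W <- if (inherits(cm, "connectivity_matrix")) cm$weights else cm
  stopifnot(is.matrix(W), nrow(W) == ncol(W), s > 0, s < 1)
  N <- nrow(W)
  ut <- which(upper.tri(W))
  w <- W[ut]
  w[is.na(w)] <- -Inf
  K <- round(s * N * (N - 1) / 2)
  if (K == 0) warning("sparsity ", s, " yields an empty graph")
  ii <- row(W)[ut]
  jj <- col(W)[ut]
  ord <- order(-w, ii, jj)
  keep <- head(ord[is.finite(w[ord])], K)
  A <- matrix(0L, N, N, dimnames = dimnames(W))
  A[ut[keep]] <- 1L
  A <- A + t(A)
  binary_graph(A)
}

#' Global efficiency of a binary graph
#'
#' Mean inverse shortest-path length over all ordered node pairs;
#' disconnected pairs contribute 0. Equals 1 for a complete graph and 0 for
#' an empty one.
#'
#' @param G A `binary_graph` or adjacency matrix.
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(G) {
  A <- as_adjacency(G)
  if (nrow(A) < 2) stop("graph must have at least 2 nodes")
  .global_efficiency_cpp(A)
}

#' Local efficiency of a binary graph
#'
#' Mean, over nodes, of the global efficiency of each node's
#' neighbor-induced subgraph (the node itself excluded); subgraphs with
#' fewer than two nodes contribute 0.
#'
#' @inheritParams global_efficiency
#' @return Scalar in \[0, 1\].
#' @export
local_efficiency <- function(G) {
  A <- as_adjacency(G)
  if (nrow(A) < 2) stop("graph must have at least 2 nodes")
  .local_efficiency_cpp(A)
}

#' Nodal efficiency of every node
#'
#' For node i, the mean inverse distance to all other nodes.
#'
#' @inheritParams global_efficiency
#' @return Numeric vector (named when the adjacency has dimnames).
#' @export
nodal_efficiency <- function(G) {
  A <- as_adjacency(G)
  if (nrow(A) < 2) stop("graph must have at least 2 nodes")
  e <- .nodal_efficiency_cpp(A)
  names(e) <- rownames(A)
  e
}

#' Degree-preserving rewiring (Maslov-Sneppen)
#'
#' Randomizes a graph by repeated double-edge swaps, preserving the exact
#' degree sequence; used to build null ensembles for efficiency
#' normalization.
#'
#' @param G A `binary_graph` or adjacency matrix.
#' @param n_swap_per_edge Attempted swaps per edge (default 10).
#' @param seed Optional integer seed.
#' @return A `binary_graph` with identical degree sequence.
#' @export
rewire_preserving_degree <- function(G, n_swap_per_edge = 10L, seed = NULL) {
  A <- as_adjacency(G)
  if (sum(A) / 2 < 2) stop("graph must have at least 2 edges")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  g2 <- igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = n_swap_per_edge * igraph::ecount(g)))
  A2 <- as.matrix(igraph::as_adjacency_matrix(g2, type = "both"))
  storage.mode(A2) <- "integer"
  dimnames(A2) <- dimnames(A)
  stopifnot(all(colSums(A2) == colSums(A)))
  binary_graph(A2)
}

#' Null ensemble of rewired graphs
#'
#' @param G A `binary_graph` or adjacency matrix.
#' @param n_null Ensemble size (default 100).
#' @param n_swap_per_edge Swaps per edge for each rewiring.
#' @param seed Optional integer seed (the ensemble is generated from it
#'   deterministically).
#' @return A `null_ensemble`: per-null `e_glob`/`e_loc` plus their means and
#'   standard deviations.
#' @export
null_ensemble <- function(G, n_null = 100L, n_swap_per_edge = 10L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eg <- numeric(n_null)
  el <- numeric(n_null)
  for (b in seq_len(n_null)) {
    Gn <- rewire_preserving_degree(G, n_swap_per_edge)
    eg[b] <- global_efficiency(Gn)
    el[b] <- local_efficiency(Gn)
  }
  structure(list(e_glob = eg, e_loc = el, n_null = as.integer(n_null),
                 mean_e_glob = mean(eg), mean_e_loc = mean(el),
                 sd_e_glob = sd(eg), sd_e_loc = sd(el)),
            class = "null_ensemble")
}

#' Normalize efficiencies against a null ensemble
#'
#' @param e_glob,e_loc Observed global and local efficiency.
#' @param ensemble A [null_ensemble()].
#' @return List with `normalized_e_glob` and `normalized_e_loc` (ratios of
#'   observed to null-mean; `NA` when a null mean is zero).
#' @export
normalize_against_null <- function(e_glob, e_loc, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"), ensemble$n_null >= 1)
  ng <- if (ensemble$mean_e_glob > 0) e_glob / ensemble$mean_e_glob else NA_real_
  nl <- if (ensemble$mean_e_loc > 0) e_loc / ensemble$mean_e_loc else NA_real_
  list(normalized_e_glob = ng, normalized_e_loc = nl)
}

#' Small-world classification from normalized efficiencies
#'
#' A network is small-world when its normalized local efficiency exceeds 1
#' while its normalized global efficiency is approximately 1 (within `tol`).
#'
#' @param normalized_e_loc,normalized_e_glob Normalized efficiencies.
#' @param tol Half-width of the "approximately 1" band (default 0.1).
#' @return Logical.
#' @export
is_small_world <- function(normalized_e_loc, normalized_e_glob, tol = 0.1) {
  stopifnot(is.finite(normalized_e_loc), is.finite(normalized_e_glob))
  normalized_e_loc > 1 && abs(normalized_e_glob - 1) <= tol
}

#' Area under a metric curve over the sparsity grid
#'
#' Trapezoidal integral of a per-sparsity metric, the threshold-free summary
#' scalar used throughout the analysis.
#'
#' @param values Metric values, one per grid point.
#' @param grid Strictly increasing sparsity grid.
#' @return Scalar AUC.
#' @export
auc_over_sparsity <- function(values, grid) {
  stopifnot(length(values) == length(grid), length(grid) >= 2,
            all(diff(grid) > 0))
  if (anyNA(values))
    stop("NaN/NA metric values at sparsity ",
         paste(grid[is.na(values)], collapse = ", "))
  pracma::trapz(grid, values)
}

#' Efficiency profile of one connectivity matrix over the sparsity grid
#'
#' Thresholds the matrix at every grid sparsity and records global, local,
#' and nodal efficiency, plus their trapezoidal AUCs.
#'
#' @param cm A `connectivity_matrix` or symmetric weight matrix.
#' @param grid Sparsity grid (default [sparsity_grid()]).
#' @return An `efficiency_profile`: list with `sparsity_grid`, `e_glob`,
#'   `e_loc` (vectors), `nodal` (grid x nodes matrix), `auc_e_glob`,
#'   `auc_e_loc`, `auc_nodal` (per-node vector).
#' @export
efficiency_profile <- function(cm, grid = sparsity_grid()) {
  eg <- numeric(length(grid))
  el <- numeric(length(grid))
  nodal <- NULL
  for (k in seq_along(grid)) {
    G <- threshold_by_sparsity(cm, grid[k])
    eg[k] <- global_efficiency(G)
    el[k] <- local_efficiency(G)
    ne <- nodal_efficiency(G)
    if (is.null(nodal)) nodal <- matrix(NA_real_, length(grid), length(ne),
                                        dimnames = list(NULL, names(ne)))
    nodal[k, ] <- ne
  }
  structure(list(sparsity_grid = grid, e_glob = eg, e_loc = el, nodal = nodal,
                 auc_e_glob = auc_over_sparsity(eg, grid),
                 auc_e_loc = auc_over_sparsity(el, grid),
                 auc_nodal = apply(nodal, 2, auc_over_sparsity, grid = grid)),
            class = "efficiency_profile")
}
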