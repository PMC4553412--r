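test_that("sparsity thresholding keeps the top-k weights with deterministic ties", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.9
  W[3, 4] <- W[4, 3] <- 0.8
  W[1, 3] <- W[3, 1] <- 0.2
  W[2, 4] <- W[4, 2] <- 0.1
  G <- threshold_by_sparsity(W, 2 / 6)  # target 2 edges
  expect_equal(G$n_edges, 2L)
  expect_equal(G$adjacency[1, 2], 1L)
  expect_equal(G$adjacency[3, 4], 1L)
  expect_equal(G$adjacency[1, 3], 0L)
  # ties broken by stable node-index order
  Wt <- matrix(0.5, 4, 4); diag(Wt) <- 0
  Gt <- threshold_by_sparsity(Wt, 2 / 6)
  expect_equal(which(Gt$adjacency[upper.tri(Gt$adjacency)] == 1), c(1L, 2L))
  # near-cap sparsity keeps everything
  set.seed(1)
  Wd <- matrix(rnorm(36), 6); Wd <- Wd + t(Wd)
  expect_equal(threshold_by_sparsity(Wd, 0.999)$n_edges, 15L)
  # missing entries are never selected
  Wn <- Wd; Wn[1, 2] <- Wn[2, 1] <- NA
  Gn <- threshold_by_sparsity(Wn, 0.999)
  expect_equal(Gn$adjacency[1, 2], 0L)
})

test_that("the printed sparsity grid has 20 thresholds and yields 20 graphs", {
  grid <- sparsity_grid()
  expect_length(grid, 20)
  expect_equal(grid[1], 0.02)
  expect_equal(grid[20], 0.40)
  set.seed(2)
  W <- matrix(rnorm(30^2), 30); W <- W + t(W)
  graphs <- lapply(grid, threshold_by_sparsity, cm = W)
  expect_length(graphs, 20)
  # realized sparsity within one edge of the target
  for (k in c(1, 10, 20)) {
    target <- round(grid[k] * 30 * 29 / 2)
    expect_lte(abs(graphs[[k]]$n_edges - target), 1)
  }
})

test_that("efficiencies reproduce closed forms", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(global_efficiency(K4), 1)
  expect_equal(local_efficiency(K4), 1)
  empty <- matrix(0, 4, 4)
  expect_equal(global_efficiency(empty), 0)
  P3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(global_efficiency(P3), 5 / 6)
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(local_efficiency(K3), 1)
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(local_efficiency(star), 0)
  expect_equal(unname(nodal_efficiency(star)), c(1, 2/3, 2/3, 2/3))
  expect_equal(nodal_efficiency(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))[3], 0)
  expect_error(global_efficiency(matrix(0, 1, 1)), "2 nodes")
})

test_that("efficiencies match the Floyd-Warshall oracle on 200 random small graphs", {
  set.seed(3)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    A <- random_adjacency(n, runif(1, 0.2, 0.9))
    expect_equal(global_efficiency(A), oracle_global_eff(A), tolerance = 1e-14)
    expect_equal(unname(nodal_efficiency(A)), unname(oracle_nodal_eff(A)),
                 tolerance = 1e-14)
    expect_equal(local_efficiency(A), oracle_local_eff(A), tolerance = 1e-14)
  }
})

test_that("global efficiency is monotone under edge addition and equals mean nodal efficiency", {
  set.seed(4)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    A <- random_adjacency(n, 0.3)
    expect_equal(mean(nodal_efficiency(A)), global_efficiency(A),
                 tolerance = 1e-12)
    absent <- which(A == 0 & upper.tri(A))
    if (length(absent) == 0) next
    pick <- sample(absent, 1)
    A2 <- A
    A2[pick] <- 1L
    A2[cbind(col(A)[pick], row(A)[pick])] <- 1L
    expect_gte(global_efficiency(A2), global_efficiency(A))
  }
})

test_that("degree-preserving rewiring keeps the exact degree sequence", {
  set.seed(5)
  A <- random_adjacency(30, 0.2)
  for (s in 1:5) {
    G2 <- rewire_preserving_degree(A, seed = s)
    expect_identical(colSums(G2$adjacency), colSums(A))
    expect_identical(diag(G2$adjacency), rep(0L, 30))
  }
  # K4 admits no degree-preserving change
  K4 <- matrix(1L, 4, 4); diag(K4) <- 0L
  expect_identical(rewire_preserving_degree(K4, seed = 1)$adjacency, K4)
  # different seeds give different adjacencies on a large graph
  set.seed(6)
  big <- random_adjacency(60, 0.3)
  r1 <- rewire_preserving_degree(big, seed = 1)$adjacency
  r2 <- rewire_preserving_degree(big, seed = 2)$adjacency
  expect_false(identical(r1, r2))
  expect_identical(colSums(r1), colSums(r2))
})

test_that("null normalization behaves on ER-like and lattice graphs", {
  set.seed(7)
  er <- random_adjacency(60, 0.25)
  ens <- null_ensemble(er, n_null = 100, seed = 8)
  expect_length(ens$e_glob, 100)
  expect_length(ens$e_loc, 100)
  nz <- normalize_against_null(global_efficiency(er), local_efficiency(er), ens)
  expect_lt(abs(nz$normalized_e_glob - 1), 0.05)
  expect_lt(abs(nz$normalized_e_loc - 1), 0.25)

  # ring lattice: clustered, so normalized local efficiency > 1 and the
  # small-world detector fires on a Watts-Strogatz-style construction
  rl <- ring_lattice(60, 3)
  g <- igraph::graph_from_adjacency_matrix(rl, mode = "undirected")
  set.seed(9)
  ws <- igraph::rewire(g, igraph::each_edge(prob = 0.2))
  A_ws <- as.matrix(igraph::as_adjacency_matrix(ws))
  ens_l <- null_ensemble(rl, n_null = 50, seed = 10)
  nz_l <- normalize_against_null(global_efficiency(rl), local_efficiency(rl), ens_l)
  expect_gt(nz_l$normalized_e_loc, 1)
  ens_ws <- null_ensemble(A_ws, n_null = 50, seed = 11)
  nz_ws <- normalize_against_null(global_efficiency(A_ws),
                                  local_efficiency(A_ws), ens_ws)
  expect_true(is_small_world(nz_ws$normalized_e_loc, nz_ws$normalized_e_glob))

  # degenerate and rule-application cases
  same <- structure(list(e_glob = rep(0.5, 3), e_loc = rep(0.4, 3), n_null = 3L,
                         mean_e_glob = 0.5, mean_e_loc = 0.4,
                         sd_e_glob = 0, sd_e_loc = 0), class = "null_ensemble")
  nz_id <- normalize_against_null(0.5, 0.4, same)
  expect_equal(nz_id$normalized_e_glob, 1)
  expect_equal(nz_id$normalized_e_loc, 1)
  expect_true(is_small_world(1.5, 1.0))
  expect_false(is_small_world(0.9, 1.0))
  expect_false(is_small_world(1.5, 1.25, tol = 0.1))
})

test_that("AUC over the sparsity grid is the trapezoidal integral", {
  grid <- sparsity_grid()
  expect_equal(auc_over_sparsity(rep(1, 20), grid), 0.38)
  expect_equal(auc_over_sparsity(rep(0, 20), grid), 0)
  ramp <- seq(0, 1, length.out = 20)
  expect_equal(auc_over_sparsity(ramp, grid), 0.19)
  expect_error(auc_over_sparsity(c(1, NA, 1), c(0.1, 0.2, 0.3)), "0.2")
})

test_that("efficiency profiles assemble per-sparsity metrics and AUCs", {
  set.seed(12)
  W <- matrix(rnorm(20^2), 20); W <- W + t(W)
  grid <- sparsity_grid(0.1, 0.4, 0.1)
  pr <- efficiency_profile(W, grid)
  expect_length(pr$e_glob, 4)
  expect_equal(dim(pr$nodal), c(4, 20))
  expect_equal(pr$auc_e_glob, auc_over_sparsity(pr$e_glob, grid))
  expect_true(all(pr$e_glob >= 0 & pr$e_glob <= 1))
  expect_true(all(diff(pr$e_glob) >= 0))  # more edges never hurt E_glob
})
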