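test_that("the orientation set has 48 isometries (24 proper rotations) incl. identity", {
  o48 <- cube_orientations(3, TRUE)
  o24 <- cube_orientations(3, FALSE)
  expect_length(o48, 48)
  expect_length(o24, 24)
  expect_equal(o48[[1]], 1:27)
  # all maps are permutations, and all distinct
  expect_true(all(vapply(o48, function(m) setequal(m, 1:27), logical(1))))
  expect_equal(length(unique(o48)), 48)
})

test_that("cube similarity recovers isometric copies exactly", {
  set.seed(1)
  a <- array(rnorm(27), c(3, 3, 3))
  b <- rotate_cube_z(a)
  expect_equal(cube_similarity(a, b), 1, tolerance = 1e-12)
  expect_equal(cube_similarity(a, a[3:1, , ]), 1, tolerance = 1e-12)  # reflection
  # reflections excluded: a pure reflection of a chiral pattern scores < 1
  expect_lt(cube_similarity(a, a[3:1, , ], include_reflections = FALSE), 1)
})

test_that("cube similarity agrees with an exhaustive-orientation oracle", {
  set.seed(2)
  for (rep in 1:5) {
    a <- array(rnorm(27), c(3, 3, 3))
    b <- array(rnorm(27), c(3, 3, 3))
    oracle <- max(vapply(oracle_all_orientations(b),
                         function(bo) cor(as.numeric(a), as.numeric(bo)),
                         numeric(1)))
    expect_equal(cube_similarity(a, b), oracle, tolerance = 1e-12)
  }
  # anticorrelated pattern: oracle bounds the achievable maximum
  a <- array(rnorm(27), c(3, 3, 3))
  b <- -a
  oracle <- max(vapply(oracle_all_orientations(b),
                       function(bo) cor(as.numeric(a), as.numeric(bo)),
                       numeric(1)))
  expect_equal(cube_similarity(a, b), oracle, tolerance = 1e-12)
})

test_that("cube similarity is symmetric, affine-invariant, and monotone in the orientation set", {
  set.seed(3)
  for (rep in 1:10) {
    a <- array(rnorm(27), c(3, 3, 3))
    b <- array(rnorm(27), c(3, 3, 3))
    s <- cube_similarity(a, b)
    expect_identical(s, cube_similarity(b, a))
    expect_equal(cube_similarity(a + 5, b), s, tolerance = 1e-12)
    expect_equal(cube_similarity(a, 3 * b), s, tolerance = 1e-12)
    expect_gte(s, cube_similarity(a, b, include_reflections = FALSE) - 1e-12)
  }
  expect_true(is.na(cube_similarity(array(1, c(3, 3, 3)),
                                    array(rnorm(27), c(3, 3, 3)))))
})

test_that("independent noise cubes show the max-statistic inflation above zero", {
  set.seed(4)
  sims <- replicate(300, cube_similarity(rnorm(27), rnorm(27)))
  expect_gt(mean(sims), 0.1)  # maximum of 48 correlated draws is biased up
  expect_lt(mean(sims), 0.7)
})

test_that("patch extraction follows the indexing and clamping conventions", {
  vol <- array(seq_len(10^3), c(10, 10, 10))
  nt <- data.frame(node_id = "a", x = 5, y = 5, z = 5)
  P <- extract_patches(vol, nt, 3)
  expect_equal(dim(P), c(27, 1))
  expect_equal(as.numeric(P), as.numeric(vol[5:7, 5:7, 5:7]))  # 0-based 4..6
  # cube_edge = 1 is the centroid voxel itself
  expect_equal(as.numeric(extract_patches(vol, nt, 1)), vol[6, 6, 6])
  # affine: voxel size 2 mm, so world (10,10,10) is voxel (5,5,5)
  vol2 <- vol
  attr(vol2, "affine") <- diag(c(2, 2, 2, 1))
  P2 <- extract_patches(vol2, data.frame(node_id = "a", x = 10, y = 10, z = 10), 3)
  expect_equal(as.numeric(P2), as.numeric(P))
  expect_warning(extract_patches(vol, data.frame(node_id = "e", x = 0, y = 5, z = 5), 3),
                 "clamped")
  expect_error(extract_patches(vol, data.frame(node_id = "o", x = 40, y = 5, z = 5), 3),
               "outside")
})

test_that("extracted patches round-trip the planted archetypes", {
  cfg <- cohort_config(n_group_a = 2, n_group_b = 2, n_nodes = 8, n_modules = 2,
                       n_timepoints = 100, gm_noise_sd = 0, zero_var_fraction = 0,
                       seed = 6)
  ps <- generate_gm_patches(synthetic_truth(cfg))
  # embed each node's cube in a volume at a known centroid and re-extract
  vol <- array(0, c(30, 30, 30))
  centroids <- data.frame(node_id = ps$node_ids,
                          x = seq(2, 23, by = 3), y = 15, z = 15)
  for (i in seq_len(8)) {
    cc <- centroids[i, ]
    vol[(cc$x - 1):(cc$x + 1) + 1, 14:16 + 1, 14:16 + 1] <-
      array(ps$patches[[1]][, i], c(3, 3, 3))
  }
  P <- extract_patches(vol, centroids, 3)
  expect_equal(unname(P), unname(ps$patches[[1]]), tolerance = 1e-12)
})

test_that("morphological networks apply positivity filtering and the exclusion rule", {
  # three identical cubes -> off-diagonal similarities all 1
  set.seed(7)
  base <- rnorm(27)
  ps <- list(patches = list(s1 = cbind(a = base, b = base, c = base)),
             cube_edge = 3L, node_ids = c("a", "b", "c"), subject_ids = "s1")
  nets <- build_morpho_network(ps)
  W <- nets[[1]]$weights
  expect_equal(unname(W[upper.tri(W)]), rep(1, 3), tolerance = 1e-12)

  # a pair with negative max-similarity is stored as 0: a radial pattern is
  # invariant under every isometry, so its negation stays at r = -1
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  x <- sqrt(rowSums(g^2))
  y <- -x
  expect_equal(cube_similarity(x, y), -1, tolerance = 1e-12)
  ps2 <- list(patches = list(s1 = cbind(a = x, b = y)), cube_edge = 3L,
              node_ids = c("a", "b"), subject_ids = "s1")
  W2 <- build_morpho_network(ps2)[[1]]$weights
  expect_equal(W2[1, 2], 0)

  # planted zero-variance fraction is excluded and reported
  cfg <- cohort_config(n_group_a = 2, n_group_b = 2, n_nodes = 100,
                       n_modules = 4, n_timepoints = 100,
                       zero_var_fraction = 0.01, seed = 8)
  psz <- generate_gm_patches(synthetic_truth(cfg))
  netz <- build_morpho_network(psz)
  rep_z <- attr(netz, "exclusion_report")
  expect_equal(rep_z$global_fraction, 0.01, tolerance = 1e-12)
  expect_true(all(is.na(netz[[1]]$weights[psz$zero_variance_nodes, ])))

  # abort when more than half the nodes are degenerate
  ps3 <- list(patches = list(s1 = cbind(a = rep(1, 27), b = rep(2, 27),
                                        c = rnorm(27))),
              cube_edge = 3L, node_ids = c("a", "b", "c"), subject_ids = "s1")
  expect_error(build_morpho_network(ps3), "50%")
})
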