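test_that("feature screening selects ~1% of null features and always finds strong effects", {
  set.seed(1)
  X <- matrix(rnorm(40 * 2000), 40, 2000)
  y <- rep(c("A", "B"), each = 20)
  sel <- select_features(X, y, p_thresh = 0.01, n_perm = 1000, seed = 2)
  expect_gt(length(sel) / 2000, 0.003)
  expect_lt(length(sel) / 2000, 0.025)

  # a planted 3-sd feature is always selected
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    Xs <- matrix(rnorm(20 * 50), 20, 50)
    Xs[11:20, 7] <- Xs[11:20, 7] + 3
    7 %in% select_features(Xs, rep(0:1, each = 10), 0.01, 500, seed = s)
  }, logical(1))
  expect_true(all(hits))

  # p_thresh = 1 selects everything
  expect_length(select_features(X[, 1:20], y, p_thresh = 1, n_perm = 50, seed = 3), 20)
  # empty selection falls back to the single best feature, with warning
  set.seed(4)
  Xn <- matrix(rnorm(20 * 5), 20, 5)
  expect_warning(s1 <- select_features(Xn, rep(0:1, each = 10), 1e-6, 200, seed = 4),
                 "smallest-p")
  expect_length(s1, 1)
})

test_that("MLDA equals classical LDA under spherical covariance", {
  skip_if_not_installed("MASS")
  set.seed(5)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3)
  y <- factor(rep(c("A", "B"), each = n / 2))
  # whiten so the pooled within-class covariance is exactly spherical,
  # making the eigenvalue flooring a no-op
  S <- ((n / 2 - 1) * cov(X[y == "A", ]) + (n / 2 - 1) * cov(X[y == "B", ])) / (n - 2)
  es <- eigen(S, symmetric = TRUE)
  X <- X %*% es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  X[y == "B", ] <- sweep(X[y == "B", ], 2, c(1, 0.5, -0.5), "+")
  m <- mlda_fit(X, y)
  ld <- MASS::lda(X, y)$scaling[, 1]
  # directions are parallel (up to scale and sign)
  cosang <- abs(sum(m$w * ld)) / (sqrt(sum(m$w^2)) * sqrt(sum(ld^2)))
  expect_gt(cosang, 0.999)
  # predictions agree with MASS::lda on training data
  expect_equal(as.character(predict(m, X)),
               as.character(predict(MASS::lda(X, y))$class))
})

test_that("MLDA stays well-posed with more features than samples", {
  set.seed(6)
  X <- matrix(rnorm(20 * 50), 20, 50)
  y <- factor(rep(c("A", "B"), each = 10))
  X[y == "B", 1:5] <- X[y == "B", 1:5] + 2
  m <- mlda_fit(X, y)
  expect_true(all(is.finite(m$w)))
  # flooring makes the shrunken covariance invertible: all eigenvalues >= mean
  expect_true(all(m$floored_eigenvalues >= mean(m$eigenvalues) - 1e-12))
  expect_lt(max(m$floored_eigenvalues) / min(m$floored_eigenvalues), 1e6)
  # two separated blobs: training accuracy 1
  expect_equal(mean(predict(m, X) == y), 1)
  expect_error(mlda_fit(X[y == "A", ], y[y == "A"]), "two classes")
})

test_that("LOOCV has no leakage, is seed-deterministic, and behaves at chance on null data", {
  set.seed(7)
  X <- matrix(rnorm(24 * 30), 24, 30)
  y <- factor(rep(c("A", "B"), each = 12))
  X[y == "B", 1:4] <- X[y == "B", 1:4] + 2.5
  r1 <- loocv_classify(X, y, n_perm_screen = 300, seed = 11)
  r2 <- loocv_classify(X, y, n_perm_screen = 300, seed = 11)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$selected, r2$selected)
  expect_equal(r1$accuracy, 1)

  # poisoning the held-out row cannot change that fold's screening/fit
  Xp <- X
  Xp[5, ] <- 1e6
  rp <- loocv_classify(Xp, y, n_perm_screen = 300, seed = 11)
  expect_identical(rp$selected[[5]], r1$selected[[5]])

  # labels independent of features: accuracy near chance
  set.seed(8)
  acc <- vapply(1:10, function(s) {
    Xn <- matrix(rnorm(36 * 20), 36, 20)
    yn <- factor(rep(c("A", "B"), c(20, 16)))
    suppressWarnings(loocv_classify(Xn, yn, n_perm_screen = 200, seed = s))$accuracy
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.17)

  # sensitivity/specificity are consistent with the confusion matrix
  cm <- r1$confusion
  expect_equal(r1$sensitivity, cm["tp"] / (cm["tp"] + cm["fn"]),
               ignore_attr = TRUE)
  expect_equal(r1$specificity, cm["tn"] / (cm["tn"] + cm["fp"]),
               ignore_attr = TRUE)
})

test_that("label-permutation significance records the full null and detects planted effects", {
  set.seed(9)
  X <- matrix(rnorm(24 * 30), 24, 30)
  y <- factor(rep(c("A", "B"), each = 12))
  X[y == "B", 1:4] <- X[y == "B", 1:4] + 2.5
  ps <- permutation_significance(X, y, n_perm = 25, n_perm_screen = 150, seed = 10)
  expect_length(ps$null_accuracy, 25)
  expect_gt(ps$z_score, 2)
  # the null distribution is centered near the majority-class rate
  expect_lt(abs(mean(ps$null_accuracy) - 0.5), 0.2)
  expect_gt(ps$observed$accuracy, quantile(ps$null_accuracy, 0.95) - 1e-12)
})
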