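#' Permutation-based feature screening
#'
#' Selects feature columns whose two-group permutation p-value (uncorrected)
#' falls below `p_thresh`. When nothing passes, the single smallest-p
#' feature is returned with a warning so that a classifier can still be
#' fitted.
#'
#' @param feature_matrix n x p matrix (rows = subjects).
#' @param labels Two-level factor or 0/1 vector.
#' @param p_thresh Selection threshold (default 0.01).
#' @param n_perm Permutations per feature test (default 1000).
#' @param seed Optional integer seed.
#' @return Integer vector of selected column indices, with attribute
#'   `"p_values"`.
#' @export
select_features <- function(feature_matrix, labels, p_thresh = 0.01,
                            n_perm = 1000L, seed = NULL) {
  X <- as.matrix(feature_matrix)
  g <- as_binary_labels(labels)
  res <- permutation_test_matrix(X, g, covariates = NULL,
                                 n_perm = n_perm, seed = seed)
  # p lives in (0, 1]; a threshold of 1 means "select everything"
  sel <- if (p_thresh >= 1) seq_len(ncol(X)) else which(res$p < p_thresh)
  if (length(sel) == 0) {
    warning("no feature passed p < ", p_thresh,
            "; falling back to the single smallest-p feature")
    sel <- which.min(res$p)
  }
  attr(sel, "p_values") <- res$p
  sel
}

as_binary_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    f <- factor(labels)
    if (nlevels(f) != 2) stop("labels must have exactly two levels")
    as.integer(f) - 1L
  } else {
    u <- sort(unique(labels))
    if (length(u) != 2) stop("labels must have exactly two levels")
    as.integer(labels == u[2])
  }
}

#' Fit a maximum-uncertainty linear discriminant (MLDA)
#'
#' Classical LDA regularized for the p > n regime: the pooled within-class
#' covariance is eigendecomposed and every eigenvalue below the eigenvalue
#' mean is floored at that mean, which makes the covariance invertible
#' regardless of the feature/sample ratio. The discriminant direction is
#' `w = S*^-1 (mu1 - mu0)` with the decision threshold at the midpoint of
#' the projected class means (equal priors).
#'
#' @param X n x p feature matrix.
#' @param y Two-level labels; the second level is the "positive" class.
#' @return An `mlda_model`.
#' @export
mlda_fit <- function(X, y) {
  X <- as.matrix(X)
  f <- if (is.factor(y)) droplevels(factor(y)) else factor(y)
  if (nlevels(f) != 2) stop("need exactly two classes")
  if (any(table(f) < 2)) stop("each class needs at least 2 samples")
  X0 <- X[f == levels(f)[1], , drop = FALSE]
  X1 <- X[f == levels(f)[2], , drop = FALSE]
  mu0 <- colMeans(X0)
  mu1 <- colMeans(X1)
  n0 <- nrow(X0); n1 <- nrow(X1)
  S <- ((n0 - 1) * cov_or_zero(X0) + (n1 - 1) * cov_or_zero(X1)) / (n0 + n1 - 2)
  ev <- eigen(S, symmetric = TRUE)
  lam_bar <- mean(ev$values)
  lam <- pmax(ev$values, lam_bar)
  if (lam_bar <= 0) stop("degenerate pooled covariance (all features constant)")
  w <- ev$vectors %*% ((1 / lam) * crossprod(ev$vectors, mu1 - mu0))
  w <- as.numeric(w)
  threshold <- sum(w * (mu1 + mu0) / 2)
  structure(list(levels = levels(f), mu0 = mu0, mu1 = mu1,
                 eigenvalues = ev$values, floored_eigenvalues = lam,
                 w = w, threshold = threshold),
            class = "mlda_model")
}

cov_or_zero <- function(X) {
  if (nrow(X) < 2) matrix(0, ncol(X), ncol(X)) else stats::cov(X)
}

#' @describeIn mlda_fit Predict class labels for new samples.
#' @param object An `mlda_model`.
#' @param newdata Matrix (or vector for a single sample) of features.
#' @param ... Unused.
#' @export
predict.mlda_model <- function(object, newdata, ...) {
  Xn <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  score <- as.numeric(Xn %*% object$w)
  factor(ifelse(score > object$threshold, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' Leave-one-out cross-validated MLDA classification
#'
#' For every held-out subject, feature screening and MLDA fitting use only
#' the remaining n - 1 subjects (no information leakage), then the held-out
#' label is predicted. Accuracy, sensitivity, and specificity are computed
#' from the pooled predictions, with the second label level (patients)
#' treated as positive. A `screen_once = TRUE` mode performs screening once
#' on the full sample before the folds — the optimistic variant some
#' analyses use — and is provided only for comparison.
#'
#' @param feature_matrix n x p matrix.
#' @param labels Two-level labels; second level = positive class.
#' @param p_thresh Screening threshold (default 0.01).
#' @param n_perm_screen Permutations per screening test (default 1000).
#' @param seed Integer seed; fold-level screening seeds derive from it.
#' @param screen_once Screen on the full sample instead of per fold
#'   (default FALSE).
#' @return A `classifier_report`: accuracy, sensitivity, specificity,
#'   per-fold selected features, pooled predictions, seed.
#' @export
loocv_classify <- function(feature_matrix, labels, p_thresh = 0.01,
                           n_perm_screen = 1000L, seed = 1L,
                           screen_once = FALSE) {
  X <- as.matrix(feature_matrix)
  f <- if (is.factor(labels)) droplevels(factor(labels)) else factor(labels)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 subjects for LOOCV")
  if (nlevels(f) != 2) stop("need exactly two classes")
  pred <- factor(rep(NA, n), levels = levels(f))
  selected <- vector("list", n)
  sel_all <- if (screen_once)
    select_features(X, f, p_thresh, n_perm_screen, seed = derive_seed(seed, "classify"))
  else NULL
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- droplevels(f[tr])
    if (nlevels(ytr) < 2)
      stop("training fold ", i, " contains a single class")
    sel <- if (screen_once) sel_all else
      suppressWarnings(select_features(X[tr, , drop = FALSE], ytr, p_thresh,
                                       n_perm_screen,
                                       seed = derive_seed(seed, paste0("fold", i))))
    fit <- mlda_fit(X[tr, sel, drop = FALSE], ytr)
    pred[i] <- predict(fit, X[i, sel, drop = FALSE])
    selected[[i]] <- sel
  }
  pos <- levels(f)[2]
  tp <- sum(pred == pos & f == pos)
  tn <- sum(pred != pos & f != pos)
  fn <- sum(pred != pos & f == pos)
  fp <- sum(pred == pos & f != pos)
  structure(list(accuracy = (tp + tn) / n,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 predictions = pred, selected = selected,
                 positive = pos, seed = seed, screen_once = screen_once),
            class = "classifier_report")
}

#' Label-permutation significance of the LOOCV accuracy
#'
#' Repeats the full cross-validation (including per-fold screening) on
#' randomly permuted labels and expresses the observed accuracy as a
#' z-score against the resulting null distribution.
#'
#' @inheritParams loocv_classify
#' @param n_perm Number of label permutations (default 100).
#' @return List with `observed` (the real-label `classifier_report`),
#'   `null_accuracy` (length `n_perm`), `z_score`, `p_empirical`
#'   (add-one upper tail), `seed`.
#' @export
permutation_significance <- function(feature_matrix, labels, n_perm = 100L,
                                     p_thresh = 0.01, n_perm_screen = 1000L,
                                     seed = 1L) {
  stopifnot(n_perm >= 20)
  f <- if (is.factor(labels)) droplevels(factor(labels)) else factor(labels)
  obs <- loocv_classify(feature_matrix, f, p_thresh, n_perm_screen, seed)
  null_acc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(derive_seed(seed, paste0("labelperm", b)))
    fb <- sample(f)
    rep_b <- suppressWarnings(
      loocv_classify(feature_matrix, fb, p_thresh, n_perm_screen,
                     seed = derive_seed(seed, paste0("nullcv", b))))
    null_acc[b] <- rep_b$accuracy
  }
  s <- sd(null_acc)
  z <- if (s > 0) (obs$accuracy - mean(null_acc)) / s else NA_real_
  if (is.na(z)) warning("null accuracy distribution has zero spread; z undefined")
  list(observed = obs, null_accuracy = null_acc, z_score = z,
       p_empirical = (sum(null_acc >= obs$accuracy) + 1) / (n_perm + 1),
       seed = seed)
}
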