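#' Covariate-adjusted permutation test for a group difference
#'
#' Freedman-Lane residual permutation: the metric is regressed on the
#' covariates (plus intercept) pooled across groups, the residuals are
#' permuted and added back to the fitted values, and the group effect
#' t-statistic is recomputed for each permuted dataset. The two-tailed
#' p-value uses the add-one estimator `(#{|t*| >= |t|} + 1) / (n_perm + 1)`,
#' so p can never be exactly 0 and its minimum is `1/(n_perm + 1)`.
#'
#' @param values_a,values_b Metric values for the two groups.
#' @param covariates Optional matrix/data.frame of covariates (rows ordered
#'   as `c(values_a, values_b)`), e.g. age and gender.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @param metric Optional metric label carried into the result.
#' @return A `group_comparison`: list with `metric`, `observed_diff`
#'   (covariate-adjusted B minus A), `t_obs`, `p`, `n_perm`, `direction`
#'   (`"B>A"` or `"B<A"`), `seed`.
#' @export
permutation_test <- function(values_a, values_b, covariates = NULL,
                             n_perm = 10000L, seed = NULL,
                             metric = "metric") {
  y <- matrix(c(values_a, values_b), ncol = 1)
  group <- rep(c(0, 1), c(length(values_a), length(values_b)))
  res <- permutation_test_matrix(y, group, covariates, n_perm, seed)
  structure(list(metric = metric, observed_diff = res$coef[1],
                 t_obs = res$t_obs[1], p = res$p[1],
                 n_perm = as.integer(n_perm),
                 direction = if (res$coef[1] >= 0) "B>A" else "B<A",
                 seed = seed),
            class = "group_comparison")
}

#' Column-wise Freedman-Lane permutation tests
#'
#' Same scheme as [permutation_test()] applied to every column of a metric
#' matrix with a shared set of permutations, as used for nodal metrics and
#' for permutation-based feature screening.
#'
#' @param Y n x p matrix of metrics (rows = subjects).
#' @param group 0/1 vector (1 = group B/patients).
#' @param covariates Optional covariate matrix/data.frame.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return List with per-column `coef` (adjusted group difference), `t_obs`,
#'   and `p`.
#' @export
permutation_test_matrix <- function(Y, group, covariates = NULL,
                                    n_perm = 10000L, seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(length(group) == n, n_perm >= 1)
  if (length(unique(group)) != 2) stop("need exactly two groups")
  if (sum(group == 0) < 2 || sum(group == 1) < 2)
    stop("each group needs at least 2 subjects")
  Z <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    C <- covariates
    if (is.data.frame(C))
      C <- stats::model.matrix(~ ., data = C)[, -1, drop = FALSE]
    C <- as.matrix(C)
    stopifnot(nrow(C) == n)
    Z <- cbind(Z, C)
  }
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    warning("dropping linearly dependent covariate column(s)")
    Z <- Z[, qz$pivot[seq_len(qz$rank)], drop = FALSE]
    qz <- qr(Z)
  }
  k <- ncol(Z)
  df <- n - k - 1
  if (df < 1) stop("not enough subjects for the covariate model")
  B <- qr.Q(qz)                              # orthonormal basis of covariates
  g_res <- group - B %*% crossprod(B, group)
  g_norm <- sqrt(sum(g_res^2))
  if (g_norm < 1e-12) stop("group indicator lies in the covariate space")
  R <- Y - B %*% crossprod(B, Y)             # reduced-model residuals
  cn <- sqrt(colSums(R^2))
  const <- cn < 1e-12
  if (any(const))
    warning(sum(const), " constant metric column(s); their p set to 1")
  r_obs <- as.numeric(crossprod(g_res, R)) / (g_norm * pmax(cn, 1e-300))
  r_obs[const] <- 0
  coef <- as.numeric(crossprod(g_res, R)) / g_norm^2  # adjusted group effect
  if (!is.null(seed)) set.seed(seed)
  # Permuting the residual rows of Y and correlating with g_res is the same
  # as correlating R with an inverse-permuted g_res, so the permutation can
  # go on the (single) group vector instead of the metric matrix.
  exceed <- numeric(ncol(Y))
  thr <- abs(r_obs) - 1e-12
  block <- 2000L
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    P <- vapply(seq_len(nb), function(i) sample.int(n), integer(n))  # n x nb
    G <- matrix(g_res[P], n, nb)             # permuted group residuals
    num <- crossprod(G, R)                   # nb x p
    if (k == 1L) {
      # residuals sum to zero, so row permutation leaves column norms fixed
      rp <- num / (g_norm * rep(pmax(cn, 1e-300), each = nb))
    } else {
      rp <- matrix(0, nb, ncol(Y))
      for (i in seq_len(nb)) {
        Bp <- B[P[, i], , drop = FALSE]
        M <- crossprod(Bp, R)                # k x p projection of permuted R
        qn2 <- pmax(cn^2 - colSums(M^2), 0)
        rp[i, ] <- num[i, ] / (g_norm * pmax(sqrt(qn2), 1e-300))
      }
    }
    exceed <- exceed + colSums(abs(rp) >= rep(thr, each = nb))
    done <- done + nb
  }
  p <- (exceed + 1) / (n_perm + 1)
  p[const] <- 1
  t_obs <- r_obs * sqrt(df / pmax(1 - r_obs^2, 1e-300))
  list(coef = coef, t_obs = t_obs, p = p, df = df)
}

#' False-positive correction at threshold 1/N
#'
#' The network-level multiple-comparison rule: a nodal p-value is declared
#' significant when it is below `1/n_nodes` (1/264 = 0.00379 for a 264-node
#' atlas).
#'
#' @param p_values Numeric vector of p-values.
#' @param n_nodes Number of nodes defining the threshold.
#' @return Logical significance mask.
#' @export
false_positive_correction <- function(p_values, n_nodes) {
  stopifnot(n_nodes >= 1, all(p_values > 0 & p_values <= 1, na.rm = TRUE))
  p_values < 1 / n_nodes
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' removal of the covariates (and intercept); the p-value uses the t
#' distribution with `n - k - 2` degrees of freedom for k covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional covariate matrix/data.frame.
#' @return A `partial_correlation_result`: list with `r`, `p`, `df`, `n`,
#'   `covariates` (column names).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  Z <- cbind(intercept = rep(1, n))
  cov_names <- character(0)
  if (!is.null(covariates)) {
    C <- covariates
    if (is.data.frame(C))
      C <- stats::model.matrix(~ ., data = C)[, -1, drop = FALSE]
    C <- as.matrix(C)
    stopifnot(nrow(C) == n)
    qc <- qr(cbind(Z, C))
    if (qc$rank < ncol(C) + 1) {
      warning("dropping linearly dependent covariate column(s)")
      keep <- qc$pivot[seq_len(qc$rank)]
      Z <- cbind(Z, C)[, sort(keep), drop = FALSE]
    } else Z <- cbind(Z, C)
    cov_names <- colnames(Z)[-1]
  }
  k <- ncol(Z) - 1
  df <- n - k - 2
  if (df < 2) stop("need n > number of covariates + 3")
  qz <- qr(Z)
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  # a variable lying in the covariate space leaves only numerical dust:
  # its adjusted association is 0 by construction
  if (sd(rx) <= 1e-10 * max(sd(x), 1) || sd(ry) <= 1e-10 * max(sd(y), 1)) {
    return(structure(list(r = 0, p = 1, df = n - k - 2, n = n,
                          covariates = cov_names),
                     class = "partial_correlation_result"))
  }
  r <- suppressWarnings(cor(rx, ry))
  if (is.na(r)) stop("zero-variance input after covariate adjustment")
  tval <- r * sqrt(df / max(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tval), df)
  structure(list(r = r, p = p, df = df, n = n, covariates = cov_names),
            class = "partial_correlation_result")
}
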