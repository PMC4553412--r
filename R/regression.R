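#' Pearson screening of candidate predictors
#'
#' Keeps the columns whose two-tailed Pearson correlation p-value against
#' the response falls below `p_thresh`.
#'
#' @param candidate_matrix n x p matrix of candidate predictors.
#' @param response Numeric response vector.
#' @param p_thresh Screening threshold (default 0.01).
#' @return Integer vector of selected columns (possibly empty), with
#'   attributes `"p_values"` and `"r"`.
#' @export
screen_predictors <- function(candidate_matrix, response, p_thresh = 0.01) {
  X <- as.matrix(candidate_matrix)
  n <- nrow(X)
  stopifnot(length(response) == n, n >= 6)
  r <- suppressWarnings(as.numeric(cor(X, response)))
  df <- n - 2
  tval <- r * sqrt(df / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tval), df)
  p[is.na(r)] <- 1  # zero-variance columns never selected
  sel <- which(p < p_thresh)
  attr(sel, "p_values") <- p
  attr(sel, "r") <- r
  sel
}

#' Least-squares multiple linear regression report
#'
#' Ordinary least squares with intercept on the selected predictors,
#' reporting the coefficients (with signs), R-squared, and the overall
#' F-test p-value. If the predictors outnumber n - 2 they are trimmed to
#' the n - 2 smallest screening p-values; collinear columns are dropped to
#' a full-rank subset.
#'
#' @param selected_matrix n x k matrix of predictors (already screened).
#' @param response Numeric response.
#' @param screening_p Optional per-column screening p-values used for
#'   trimming when k > n - 2.
#' @param response_id Label carried into the report.
#' @return A `regression_report`: list with `response_id`, `predictors`,
#'   `coefficients`, `r_squared`, `f_p_value`, `n`, `df_residual`.
#' @export
fit_mlrm <- function(selected_matrix, response, screening_p = NULL,
                     response_id = "response") {
  X <- as.matrix(selected_matrix)
  n <- nrow(X)
  stopifnot(length(response) == n)
  if (ncol(X) == 0) stop("no predictors supplied; report a no-model result instead")
  if (ncol(X) > n - 2) {
    keep_n <- n - 2
    ord <- if (!is.null(screening_p)) order(screening_p)[seq_len(keep_n)]
    else seq_len(keep_n)
    warning("more predictors (", ncol(X), ") than n - 2 = ", n - 2,
            "; keeping the ", keep_n, " smallest-p predictors")
    X <- X[, sort(ord), drop = FALSE]
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  dat <- data.frame(.y = response, X, check.names = FALSE)
  fit <- lm(.y ~ ., data = dat)
  cf <- coef(fit)
  if (anyNA(cf)) {
    drop_cols <- names(cf)[is.na(cf)][names(cf)[is.na(cf)] != "(Intercept)"]
    warning("dropping collinear predictor(s): ",
            paste(drop_cols, collapse = ", "))
    X <- X[, setdiff(colnames(X), gsub("^`|`$", "", drop_cols)), drop = FALSE]
    dat <- data.frame(.y = response, X, check.names = FALSE)
    fit <- lm(.y ~ ., data = dat)
    cf <- coef(fit)
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  f_p <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(response_id = response_id,
                 predictors = colnames(X),
                 coefficients = cf,
                 r_squared = sm$r.squared,
                 f_p_value = f_p,
                 n = n, df_residual = fit$df.residual,
                 fit = fit),
            class = "regression_report")
}

#' Screened regression of a response on nodal features
#'
#' Convenience wrapper: Pearson-screen the candidate columns at `p_thresh`,
#' then fit the least-squares model. Returns a "no model" result (class
#' `regression_report`, `r_squared = NA`) when nothing passes screening.
#'
#' @inheritParams screen_predictors
#' @inheritParams fit_mlrm
#' @param p_thresh Screening threshold (default 0.01).
#' @return A `regression_report`; when no predictor passes,
#'   `predictors` is empty and `r_squared`/`f_p_value` are `NA`.
#' @export
screened_mlrm <- function(candidate_matrix, response, p_thresh = 0.01,
                          response_id = "response") {
  X <- as.matrix(candidate_matrix)
  sel <- screen_predictors(X, response, p_thresh)
  if (length(sel) == 0) {
    return(structure(list(response_id = response_id, predictors = character(0),
                          coefficients = numeric(0), r_squared = NA_real_,
                          f_p_value = NA_real_, n = nrow(X),
                          df_residual = NA_integer_, fit = NULL,
                          no_model = TRUE),
                     class = "regression_report"))
  }
  fit_mlrm(X[, sel, drop = FALSE], response,
           screening_p = attr(sel, "p_values")[sel], response_id = response_id)
}

#' Cross-modal efficiency association
#'
#' Screened regression linking the two network modalities: a summary
#' efficiency of one modality (e.g., functional network AUC local
#' efficiency, one value per subject) is described from the other
#' modality's nodal efficiency pattern, in either direction.
#'
#' @param response_summary Numeric vector (one value per subject): the
#'   response modality's network efficiency.
#' @param predictor_nodal Subjects x nodes matrix: the predictor modality's
#'   nodal efficiencies (subject order must match).
#' @param p_thresh Screening threshold (default 0.01).
#' @param response_id Label for the report.
#' @return A `regression_report`.
#' @export
cross_modal_link <- function(response_summary, predictor_nodal,
                             p_thresh = 0.01, response_id = "cross_modal") {
  X <- as.matrix(predictor_nodal)
  if (length(response_summary) != nrow(X))
    stop("subject counts of response and predictor matrices differ")
  if (!is.null(names(response_summary)) && !is.null(rownames(X)) &&
      !identical(names(response_summary), rownames(X)))
    stop("subject ids of response and predictor matrices are misaligned")
  screened_mlrm(X, response_summary, p_thresh, response_id = response_id)
}
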