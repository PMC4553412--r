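#' Discard initial volumes from a time-series panel
#'
#' Drops the first `n_discard` timepoints of every subject, the standard
#' allowance for scanner stabilization.
#'
#' @param panel A `roi_panel`.
#' @param n_discard Number of initial timepoints to drop (default 5).
#' @return The panel with shortened series.
#' @export
discard_initial <- function(panel, n_discard = 5L) {
  stopifnot(inherits(panel, "roi_panel"), n_discard >= 0)
  nt <- nrow(panel$subjects[[1]])
  if (n_discard >= nt)
    stop("n_discard (", n_discard, ") must be smaller than the number of timepoints (", nt, ")")
  if (n_discard == 0) return(panel)
  panel$subjects <- lapply(panel$subjects, function(x)
    x[-seq_len(n_discard), , drop = FALSE])
  panel
}

# Build the per-subject confound design: intercept + linear trend always,
# plus any user-supplied columns; drops rank-deficient columns with a warning.
confound_design <- function(nt, extra = NULL) {
  X <- cbind(intercept = rep(1, nt), trend = seq_len(nt) - (nt + 1) / 2)
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    stopifnot(nrow(extra) == nt)
    X <- cbind(X, extra)
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    keep <- q$pivot[seq_len(q$rank)]
    warning("dropping ", ncol(X) - q$rank, " linearly dependent confound column(s)")
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

#' Regress nuisance signals out of a panel
#'
#' Removes, by ordinary least squares, an intercept, a linear trend, and any
#' per-subject confound columns (e.g., motion parameters, tissue means) from
#' every node's time course; the returned residuals are orthogonal to the
#' confound column space.
#'
#' @param panel A `roi_panel`.
#' @param confounds `NULL`, or a list (named by subject id or in panel order)
#'   of timepoints x k confound matrices.
#' @return The panel of residual series.
#' @export
regress_nuisance <- function(panel, confounds = NULL) {
  stopifnot(inherits(panel, "roi_panel"))
  for (s in seq_along(panel$subjects)) {
    X <- panel$subjects[[s]]
    extra <- NULL
    if (!is.null(confounds)) {
      extra <- if (!is.null(names(confounds)))
        confounds[[panel$subject_ids[s]]] else confounds[[s]]
    }
    C <- confound_design(nrow(X), extra)
    fit <- lm.fit(C, X)
    res <- as.matrix(fit$residuals)
    dimnames(res) <- dimnames(X)
    panel$subjects[[s]] <- res
  }
  panel
}

#' Band-pass filter a panel
#'
#' Zero-phase (forward-backward) Butterworth band-pass applied to every node
#' series. The defaults retain 0.01-0.1 Hz, the conventional resting-state
#' band for low-frequency fluctuations.
#'
#' @param panel A `roi_panel`.
#' @param f_lo,f_hi Band edges in Hz; `f_lo = 0` degrades to a low-pass and
#'   `f_hi` at Nyquist to a high-pass; both together are the identity.
#' @param order Butterworth order (default 4).
#' @return The filtered panel.
#' @export
bandpass <- function(panel, f_lo = 0.01, f_hi = 0.1, order = 4L) {
  stopifnot(inherits(panel, "roi_panel"))
  nyq <- 1 / (2 * panel$tr_seconds)
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= nyq))
    stop("require 0 <= f_lo < f_hi <= Nyquist (", nyq, " Hz)")
  lo <- f_lo / nyq
  hi <- f_hi / nyq
  if (lo <= 0 && hi >= 1) return(panel)
  flt <- if (lo <= 0) signal::butter(order, hi, type = "low")
  else if (hi >= 1) signal::butter(order, lo, type = "high")
  else signal::butter(order, c(lo, hi), type = "pass")
  panel$subjects <- lapply(panel$subjects, function(X) {
    Y <- apply(X, 2, function(z) signal::filtfilt(flt, z))
    dimnames(Y) <- dimnames(X)
    Y
  })
  panel
}

#' Temporal preprocessing pipeline for ROI time series
#'
#' Applies, in order: initial-volume discard, optional band-pass filtering,
#' then detrending plus nuisance regression. The band-pass stage is optional
#' because its conventional 0.01-0.1 Hz band excludes the finest wavelet
#' scale (0.125-0.25 Hz at TR = 2 s); disable it when all wavelet scales are
#' of interest.
#'
#' @param panel A `roi_panel`.
#' @param n_discard Initial volumes to drop (default 5).
#' @param do_bandpass Logical; apply the band-pass stage (default TRUE).
#' @param f_lo,f_hi Band edges in Hz.
#' @param confounds Optional per-subject confound matrices (see
#'   [regress_nuisance()]); intercept and trend are always included.
#' @return The preprocessed panel, with attribute `"prep_log"` recording the
#'   stages applied.
#' @export
prep_panel <- function(panel, n_discard = 5L, do_bandpass = TRUE,
                       f_lo = 0.01, f_hi = 0.1, confounds = NULL) {
  log <- character(0)
  panel <- discard_initial(panel, n_discard)
  log <- c(log, sprintf("discard_initial(n=%d)", n_discard))
  if (do_bandpass) {
    panel <- bandpass(panel, f_lo, f_hi)
    log <- c(log, sprintf("bandpass(%.4g-%.4g Hz)", f_lo, f_hi))
  }
  panel <- regress_nuisance(panel, confounds)
  log <- c(log, "regress_nuisance(intercept+trend)")
  attr(panel, "prep_log") <- log
  panel
}
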