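#' Wavelet filters for the MODWT
#'
#' Scaling (low-pass) filter coefficients in the Percival-Walden convention;
#' the wavelet (high-pass) filter follows by the quadrature-mirror relation
#' `h_l = (-1)^l g_{L-1-l}`. `"la8"` is the Daubechies least-asymmetric
#' 8-tap filter, the de facto standard for fMRI MODWT analysis; `"haar"` and
#' `"d4"` are provided for testing and comparison.
#'
#' @param name One of `"haar"`, `"d4"`, `"la8"`.
#' @return List with elements `g` (scaling) and `h` (wavelet) filters.
#' @export
modwt_filters <- function(name = c("la8", "d4", "haar")) {
  name <- match.arg(name)
  g <- switch(name,
    haar = c(0.7071067811865476, 0.7071067811865476),
    d4 = c(0.4829629131445342, 0.8365163037378079,
           0.2241438680420134, -0.1294095225512604),
    la8 = c(0.0322231006040427, -0.0126039672620378, -0.0992195435768472,
            0.2978577956052774, 0.8037387518059161, 0.4976186676320155,
            -0.0296355276459985, -0.0757657147892733))
  L <- length(g)
  h <- (-1)^(0:(L - 1)) * rev(g)
  list(g = g, h = h, name = name)
}

# One MODWT level applied to all columns of a matrix at once: circular
# filtering with the filter upsampled by 2^(j-1).
modwt_level <- function(V, filt, j) {
  N <- nrow(V)
  tau <- 2^(j - 1)
  out <- matrix(0, N, ncol(V))
  for (l in seq_along(filt)) {
    idx <- ((seq_len(N) - 1 - tau * (l - 1)) %% N) + 1
    out <- out + filt[l] * V[idx, , drop = FALSE]
  }
  out
}

#' Maximal-overlap discrete wavelet transform of a matrix of series
#'
#' Non-decimated pyramid MODWT: every level's detail coefficients have the
#' same length as the input, and for periodic boundaries the transform
#' partitions energy exactly across detail levels plus the final smooth.
#'
#' @param X Numeric matrix, timepoints x series (a vector is treated as one
#'   column).
#' @param wavelet Filter name for [modwt_filters()].
#' @param J Decomposition depth (number of detail levels).
#' @param boundary `"periodic"` (circular, the default) or `"reflection"`
#'   (series extended by its mirror image before circular filtering).
#' @return List with `details` (list of J matrices, each timepoints x
#'   series), `smooth` (the level-J scaling coefficients), `wavelet`, `J`,
#'   `boundary`.
#' @export
modwt <- function(X, wavelet = "la8", J = 4L, boundary = c("periodic", "reflection")) {
  boundary <- match.arg(boundary)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  f <- modwt_filters(wavelet)
  N0 <- nrow(X)
  L <- length(f$g)
  max_j <- floor(log2((N0 - 1) / (L - 1) + 1))
  if (J < 1) stop("J must be >= 1")
  if ((2^J - 1) * (L - 1) + 1 > N0)
    stop("series of length ", N0, " too short for level ", J,
         " with the ", f$name, " filter; maximum feasible J is ", max_j)
  refl <- boundary == "reflection"
  V <- if (refl) rbind(X, X[nrow(X):1, , drop = FALSE]) else X
  gt <- f$g / sqrt(2)
  ht <- f$h / sqrt(2)
  details <- vector("list", J)
  for (j in seq_len(J)) {
    W <- modwt_level(V, ht, j)
    V <- modwt_level(V, gt, j)
    details[[j]] <- if (refl) W[seq_len(N0), , drop = FALSE] else W
  }
  smooth <- if (refl) V[seq_len(N0), , drop = FALSE] else V
  for (j in seq_len(J)) dimnames(details[[j]]) <- dimnames(X)
  dimnames(smooth) <- dimnames(X)
  list(details = details, smooth = smooth, wavelet = f$name, J = as.integer(J),
       boundary = boundary)
}

#' MODWT decomposition of a time-series panel
#'
#' @param panel A `roi_panel`.
#' @param wavelet Filter name (default `"la8"`).
#' @param J Number of scales (default 4).
#' @param boundary Boundary mode passed to [modwt()].
#' @return A `wavelet_scale_set`: per subject the MODWT detail matrices for
#'   scales 1..J plus the level-J smooth, with the panel's node order.
#' @export
modwt_decompose <- function(panel, wavelet = "la8", J = 4L,
                            boundary = "periodic") {
  stopifnot(inherits(panel, "roi_panel"))
  subjects <- lapply(panel$subjects, modwt, wavelet = wavelet, J = J,
                     boundary = boundary)
  structure(list(subjects = subjects, subject_ids = panel$subject_ids,
                 group = panel$group, node_ids = panel$node_ids,
                 tr_seconds = panel$tr_seconds, wavelet = wavelet,
                 J = as.integer(J), boundary = boundary),
            class = "wavelet_scale_set")
}

#' Frequency band of a wavelet scale
#'
#' Scale j of the MODWT isolates the band `[1/2^(j+1), 1/2^j]` cycles per
#' sample, i.e. `[1/(2^(j+1) dt), 1/(2^j dt)]` Hz for sampling interval
#' `dt`. At TR = 2 s this gives 0.125-0.25 Hz (scale 1), 0.0625-0.125 Hz
#' (scale 2), 0.03125-0.0625 Hz (scale 3) and 0.015625-0.03125 Hz (scale 4).
#'
#' @param j Scale index (>= 1).
#' @param tr_seconds Sampling interval in seconds.
#' @return Numeric vector `c(f_lo_hz, f_hi_hz)`.
#' @export
scale_band <- function(j, tr_seconds) {
  stopifnot(j >= 1, tr_seconds > 0)
  c(f_lo_hz = 1 / (2^(j + 1) * tr_seconds), f_hi_hz = 1 / (2^j * tr_seconds))
}

#' Construct a connectivity matrix object
#'
#' @param weights Symmetric node x node matrix; the diagonal is set to `NA`
#'   (it is never used downstream).
#' @param modality `"functional"` or `"morphological"`.
#' @param scale Wavelet scale index, or `NA` for morphological networks.
#' @param subject_id Optional subject label.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, modality = c("functional", "morphological"),
                                scale = NA_integer_, subject_id = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  asym <- max(abs(weights - t(weights)), na.rm = TRUE)
  if (is.finite(asym) && asym > 1e-12)
    stop("connectivity weights must be symmetric (max asymmetry ", asym, ")")
  diag(weights) <- NA_real_
  structure(list(weights = weights, modality = modality, scale = scale,
                 subject_id = subject_id),
            class = "connectivity_matrix")
}

#' Wavelet-correlation functional connectivity
#'
#' For each subject, the Pearson correlation between the scale-`j` MODWT
#' detail coefficients of every node pair. Nodes with zero coefficient
#' variance get `NA` rows/columns and are reported.
#'
#' @param scale_set A `wavelet_scale_set` from [modwt_decompose()].
#' @param j Scale index (must be `<= J` of the decomposition).
#' @return Named list of `connectivity_matrix` objects (one per subject),
#'   with attribute `"zero_variance"`: per-subject character vector of
#'   excluded node ids.
#' @export
wavelet_correlation <- function(scale_set, j) {
  stopifnot(inherits(scale_set, "wavelet_scale_set"))
  if (j < 1 || j > scale_set$J)
    stop("scale ", j, " not present (J = ", scale_set$J, ")")
  zv <- list()
  out <- lapply(seq_along(scale_set$subjects), function(s) {
    W <- scale_set$subjects[[s]]$details[[j]]
    v <- apply(W, 2, var)
    bad <- v <= 0 | !is.finite(v)
    R <- suppressWarnings(cor(W))
    if (any(bad)) {
      R[bad, ] <- NA_real_
      R[, bad] <- NA_real_
      zv[[scale_set$subject_ids[s]]] <<- scale_set$node_ids[bad]
    }
    connectivity_matrix(R, "functional", scale = j,
                        subject_id = scale_set$subject_ids[s])
  })
  names(out) <- scale_set$subject_ids
  attr(out, "zero_variance") <- zv
  out
}
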