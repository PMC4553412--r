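# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: distances by Floyd-Warshall, MODWT by explicit
# DFT-domain equivalent filters, cube rotations by aperm/index reversal.

fw_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A != 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_global_eff <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  invd <- 1 / fw_distances(A)
  diag(invd) <- 0
  sum(invd) / (n * (n - 1))
}

oracle_nodal_eff <- function(A) {
  n <- nrow(A)
  invd <- 1 / fw_distances(A)
  diag(invd) <- 0
  rowSums(invd) / (n - 1)
}

oracle_local_eff <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2) return(0)
    oracle_global_eff(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

random_adjacency <- function(n, p_edge) {
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- rbinom(length(ut), 1, p_edge)
  A + t(A)
}

ring_lattice <- function(n, k = 2) {
  A <- matrix(0L, n, n)
  for (d in seq_len(k)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + d) %% n) + 1
      A[i, j] <- A[j, i] <- 1L
    }
  }
  A
}

# DFT-domain MODWT: detail coefficients are the circular filtering of x with
# the level-j equivalent filter, built by cascading the rescaled wavelet and
# scaling transfer functions.
modwt_fft_oracle <- function(x, wavelet = "la8", J = 4) {
  f <- conneff::modwt_filters(wavelet)
  gt <- f$g / sqrt(2)
  ht <- f$h / sqrt(2)
  N <- length(x)
  freqs <- (seq_len(N) - 1) / N
  transfer <- function(filt, fr)
    vapply(fr, function(u) sum(filt * exp(-2i * pi * u * (seq_along(filt) - 1))),
           complex(1))
  X <- fft(x)
  details <- vector("list", J)
  for (j in seq_len(J)) {
    Hj <- transfer(ht, 2^(j - 1) * freqs)
    if (j > 1)
      for (l in 0:(j - 2)) Hj <- Hj * transfer(gt, 2^l * freqs)
    details[[j]] <- Re(fft(X * Hj, inverse = TRUE)) / N
  }
  details
}

# Rotate a cube array 90 degrees about the third axis (independent of
# cube_orientations' signed-permutation construction).
rotate_cube_z <- function(a) {
  b <- aperm(a, c(2, 1, 3))
  b[dim(b)[1]:1, , , drop = FALSE]
}

# All 48 cube isometries generated by composing axis rotations/reflections,
# as plain array operations.
oracle_all_orientations <- function(a) {
  rots <- list(identity,
               function(x) aperm(x, c(2, 1, 3))[dim(x)[2]:1, , , drop = FALSE],
               function(x) aperm(x, c(1, 3, 2))[, dim(x)[3]:1, , drop = FALSE],
               function(x) aperm(x, c(3, 2, 1))[, , dim(x)[1]:1, drop = FALSE])
  seen <- list()
  frontier <- list(a)
  key <- function(x) paste(signif(as.numeric(x), 12), collapse = ",")
  seen[[key(a)]] <- a
  while (length(frontier)) {
    nxt <- list()
    for (x in frontier) {
      for (r in rots) {
        y <- r(x)
        k <- key(y)
        if (is.null(seen[[k]])) {
          seen[[k]] <- y
          nxt[[length(nxt) + 1]] <- y
        }
      }
      refl <- x[dim(x)[1]:1, , , drop = FALSE]
      k <- key(refl)
      if (is.null(seen[[k]])) {
        seen[[k]] <- refl
        nxt[[length(nxt) + 1]] <- refl
      }
    }
    frontier <- nxt
  }
  unname(seen)
}

# Small synthetic cohort settings shared by the slower tests.
small_cohort <- function(seed = 1, n_timepoints = 120L, ...) {
  cohort_config(n_group_a = 8L, n_group_b = 8L, n_nodes = 40L,
                n_timepoints = n_timepoints, n_modules = 4L, seed = seed, ...)
}
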