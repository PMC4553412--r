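#' Orientation maps for a voxel cube
#'
#' Enumerates the isometries of a cube — the 24 proper rotations, plus their
#' 24 reflected counterparts when `include_reflections = TRUE` — as index
#' permutations of the flattened `cube_edge^3` voxel vector. The first map is
#' always the identity.
#'
#' @param cube_edge Odd cube edge length in voxels.
#' @param include_reflections Include improper isometries (default TRUE,
#'   giving 48 maps; FALSE gives the 24 rotations).
#' @return List of integer index vectors of length `cube_edge^3`.
#' @export
cube_orientations <- function(cube_edge, include_reflections = TRUE) {
  stopifnot(cube_edge %% 2 == 1, cube_edge >= 1)
  c0 <- cube_edge
  h <- (c0 - 1) / 2
  grid <- as.matrix(expand.grid(i = 0:(c0 - 1), j = 0:(c0 - 1), k = 0:(c0 - 1)))
  centered <- grid - h
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  perm_sign <- c(1, -1, -1, 1, 1, -1)
  signs <- as.matrix(expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1)))
  maps <- list()
  for (pi in seq_along(perms)) {
    for (si in seq_len(nrow(signs))) {
      det <- perm_sign[pi] * prod(signs[si, ])
      if (!include_reflections && det < 0) next
      rotated <- sweep(centered[, perms[[pi]], drop = FALSE], 2,
                       signs[si, ], "*") + h
      idx <- as.integer(rotated[, 1] + c0 * rotated[, 2] +
                          c0^2 * rotated[, 3] + 1)
      maps[[length(maps) + 1]] <- idx
    }
  }
  # identity first, for readability of downstream maxima
  is_id <- vapply(maps, function(m) all(m == seq_len(c0^3)), logical(1))
  c(maps[is_id], maps[!is_id])
}

#' Rotation-maximized similarity between two gray-matter cubes
#'
#' The Pearson correlation between the two flattened cubes, maximized over
#' the cube's isometries applied to either patch, which makes the measure
#' exactly symmetric. A zero-variance patch yields `NA`.
#'
#' @param patch_a,patch_b Numeric vectors or arrays with `cube_edge^3`
#'   elements.
#' @param orientations Optional precomputed [cube_orientations()] list (must
#'   match the patch size); computed on the fly otherwise.
#' @param include_reflections Passed to [cube_orientations()] when
#'   `orientations` is not supplied.
#' @return Similarity in \[-1, 1\], or `NA` for a zero-variance patch.
#' @export
cube_similarity <- function(patch_a, patch_b, orientations = NULL,
                            include_reflections = TRUE) {
  a <- as.numeric(patch_a)
  b <- as.numeric(patch_b)
  stopifnot(length(a) == length(b))
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  if (is.null(orientations)) {
    edge <- round(length(a)^(1 / 3))
    stopifnot(edge^3 == length(a))
    orientations <- cube_orientations(edge, include_reflections)
  }
  best <- -Inf
  for (idx in orientations) {
    best <- max(best, cor(a, b[idx]), cor(a[idx], b))
  }
  best
}

#' Extract gray-matter cube patches around node centroids
#'
#' Cuts one `cube_edge`-sided cube per node out of a 3-D gray-matter volume,
#' centered on the node centroid. Centroids are given in world (mm)
#' coordinates and mapped to 0-based voxel indices through the volume's
#' affine; cubes that would protrude beyond the volume are clamped inward
#' with a warning.
#'
#' @param gm_volume 3-D numeric array; world coordinates are mapped through
#'   `attr(gm_volume, "affine")` (a 4x4 voxel-to-world matrix, 0-based voxel
#'   convention) when present, otherwise centroids are taken as voxel
#'   indices directly. NIfTI files can be read with `RNifti::readNifti()`
#'   and passed here with their `xform` as the affine.
#' @param node_table data.frame with columns `node_id`, `x`, `y`, `z`.
#' @param cube_edge Odd cube edge length (default 3).
#' @return Matrix `cube_edge^3` x nodes of flattened patches (columns named
#'   by node id).
#' @export
extract_patches <- function(gm_volume, node_table, cube_edge = 3L) {
  stopifnot(length(dim(gm_volume)) == 3, cube_edge %% 2 == 1)
  stopifnot(all(c("node_id", "x", "y", "z") %in% names(node_table)))
  dims <- dim(gm_volume)
  aff <- attr(gm_volume, "affine")
  world <- as.matrix(node_table[, c("x", "y", "z")])
  vox <- if (!is.null(aff)) {
    w1 <- cbind(world, 1)
    v <- t(solve(aff) %*% t(w1))[, 1:3, drop = FALSE]
    round(v)
  } else round(world)
  outside <- vox[, 1] < 0 | vox[, 1] >= dims[1] |
    vox[, 2] < 0 | vox[, 2] >= dims[2] |
    vox[, 3] < 0 | vox[, 3] >= dims[3]
  if (any(outside))
    stop("node centroid(s) outside the volume: ",
         paste(node_table$node_id[outside], collapse = ", "))
  h <- (cube_edge - 1) / 2
  lo <- pmax(vox - h, 0)
  shift <- lo - (vox - h)
  hi_over <- (vox + h) - (dims[col(vox)] - 1)
  # clamp cube inside the volume on both sides
  clamped <- FALSE
  P <- matrix(NA_real_, cube_edge^3, nrow(node_table),
              dimnames = list(NULL, node_table$node_id))
  for (i in seq_len(nrow(node_table))) {
    ctr <- vox[i, ]
    lo_i <- ctr - h
    hi_i <- ctr + h
    for (d in 1:3) {
      if (lo_i[d] < 0) { hi_i[d] <- hi_i[d] - lo_i[d]; lo_i[d] <- 0; clamped <- TRUE }
      if (hi_i[d] > dims[d] - 1) {
        lo_i[d] <- lo_i[d] - (hi_i[d] - (dims[d] - 1)); hi_i[d] <- dims[d] - 1
        clamped <- TRUE
      }
    }
    P[, i] <- as.numeric(gm_volume[(lo_i[1]:hi_i[1]) + 1,
                                   (lo_i[2]:hi_i[2]) + 1,
                                   (lo_i[3]:hi_i[3]) + 1])
  }
  if (clamped) warning("some cubes were clamped to fit inside the volume")
  P
}

#' Build per-subject morphological networks from gray-matter patches
#'
#' All-pairs rotation-maximized cube similarity per subject, with negative
#' similarities set to zero (only positive similarity is interpreted as
#' morphological connectivity) and zero-variance nodes excluded and
#' reported. Binarization is deferred to the shared sparsity grid of the
#' graph-metric stage.
#'
#' @param patch_set A `gm_patch_set` (see [generate_gm_patches()]), or any
#'   list with `patches` (per-subject `cube_edge^3` x nodes matrices),
#'   `cube_edge`, `node_ids`, `subject_ids`.
#' @param include_reflections Use all 48 isometries (default) or only the 24
#'   proper rotations.
#' @return Named list of `connectivity_matrix` objects, with attribute
#'   `"exclusion_report"`: list with per-subject excluded node ids and the
#'   global excluded fraction.
#' @export
build_morpho_network <- function(patch_set, include_reflections = TRUE) {
  stopifnot(!is.null(patch_set$patches), !is.null(patch_set$cube_edge))
  orient <- cube_orientations(patch_set$cube_edge, include_reflections)
  excluded <- list()
  nets <- lapply(seq_along(patch_set$patches), function(s) {
    P <- patch_set$patches[[s]]
    sds <- apply(P, 2, sd)
    bad <- sds == 0 | !is.finite(sds)
    if (mean(bad) > 0.5)
      stop("more than 50% of nodes have zero-variance patches for subject ",
           patch_set$subject_ids[s])
    M <- matrix(-Inf, ncol(P), ncol(P))
    for (idx in orient) {
      Co <- suppressWarnings(cor(P, P[idx, , drop = FALSE]))
      M <- pmax(M, Co, na.rm = TRUE)
    }
    M <- pmax(M, t(M))        # exact symmetry of the orientation maximum
    M[which(M < 0)] <- 0      # positivity filter
    M[bad, ] <- NA_real_
    M[, bad] <- NA_real_
    dimnames(M) <- list(patch_set$node_ids, patch_set$node_ids)
    if (any(bad))
      excluded[[patch_set$subject_ids[s]]] <<- patch_set$node_ids[bad]
    connectivity_matrix(M, "morphological",
                        subject_id = patch_set$subject_ids[s])
  })
  names(nets) <- patch_set$subject_ids
  n_total <- length(patch_set$patches) * length(patch_set$node_ids)
  frac <- sum(lengths(excluded)) / n_total
  attr(nets, "exclusion_report") <- list(excluded_nodes = excluded,
                                         global_fraction = frac)
  nets
}
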