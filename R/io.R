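#' Write / read a time-series panel as per-subject TSV
#'
#' One file per subject (`<subject_id>.tsv`), timepoints x nodes with node
#' ids as header, plus `panel.json` recording TR, subject order, and group.
#'
#' @param panel A `roi_panel`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(panel$subjects)) {
    write.table(panel$subjects[[s]],
                file.path(dir, paste0(panel$subject_ids[s], ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(tr_seconds = panel$tr_seconds, subject_ids = panel$subject_ids,
         group = as.character(panel$group), node_ids = panel$node_ids),
    file.path(dir, "panel.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "panel.json"),
                              simplifyVector = TRUE)
  subjects <- lapply(meta$subject_ids, function(id)
    as.matrix(read.delim(file.path(dir, paste0(id, ".tsv")),
                         check.names = FALSE)))
  names(subjects) <- meta$subject_ids
  structure(list(subjects = subjects, subject_ids = meta$subject_ids,
                 group = factor(meta$group), node_ids = meta$node_ids,
                 tr_seconds = meta$tr_seconds),
            class = "roi_panel")
}

#' Write a connectivity matrix as square TSV plus JSON sidecar
#'
#' @param cm A `connectivity_matrix`.
#' @param path Output TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  W <- cm$weights
  write.table(cbind(node_id = rownames(W) %||% as.character(seq_len(nrow(W))),
                    as.data.frame(W)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(subject = cm$subject_id, modality = cm$modality,
                            scale = cm$scale),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  W <- as.matrix(d[, -1, drop = FALSE])
  rownames(W) <- d[[1]]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  connectivity_matrix(W, meta$modality,
                      scale = meta$scale %||% NA_integer_,
                      subject_id = meta$subject)
}

#' Write the cohort (clinical) table as TSV
#'
#' @param cohort_table data.frame from [generate_clinical()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort_table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(cohort_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$group <- factor(d$group)
  d$gender <- factor(d$gender, levels = c("F", "M"))
  d
}

#' Write / read a gray-matter patch set as per-subject TSV
#'
#' One file per subject (`<subject_id>.tsv`, rows = flattened cube voxels,
#' columns = nodes) plus `patches.json` with the cube edge, node order, and
#' group labels.
#'
#' @param patch_set A `gm_patch_set`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_patches <- function(patch_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(patch_set$patches)) {
    write.table(patch_set$patches[[s]],
                file.path(dir, paste0(patch_set$subject_ids[s], ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(cube_edge = patch_set$cube_edge, node_ids = patch_set$node_ids,
         subject_ids = patch_set$subject_ids,
         group = as.character(patch_set$group),
         zero_variance_nodes = patch_set$zero_variance_nodes),
    file.path(dir, "patches.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_patches
#' @export
read_patches <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "patches.json"),
                              simplifyVector = TRUE)
  patches <- lapply(meta$subject_ids, function(id)
    as.matrix(read.delim(file.path(dir, paste0(id, ".tsv")),
                         check.names = FALSE)))
  names(patches) <- meta$subject_ids
  structure(list(patches = patches, cube_edge = as.integer(meta$cube_edge),
                 node_ids = meta$node_ids, subject_ids = meta$subject_ids,
                 group = factor(meta$group),
                 zero_variance_nodes = meta$zero_variance_nodes %||% character(0)),
            class = "gm_patch_set")
}
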