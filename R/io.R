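# Plain-text I/O for the pipeline's tabular artifacts.

behavior_cols <- c("observation_id", "patient_id", "group", "obs_index",
                   "task_id", "raw_score")

#' Write / read a behavior table (TSV)
#'
#' Long format with columns `observation_id`, `patient_id`, `group`,
#' `obs_index`, `task_id`, `raw_score`.
#'
#' @param behavior data.frame with the columns above.
#' @param path TSV file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_behavior_tsv <- function(behavior, path) {
  missing <- setdiff(behavior_cols, names(behavior))
  if (length(missing))
    stop("behavior table missing column(s): ", paste(missing, collapse = ", "))
  utils::write.table(behavior[, behavior_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_tsv
#' @export
read_behavior_tsv <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  missing <- setdiff(behavior_cols, names(tab))
  if (length(missing))
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  if (!is.numeric(tab$raw_score))
    stop("parse error in ", path, ": field raw_score is not numeric")
  tab
}

#' Write / read FSL-style gradient files
#'
#' `<prefix>.bvec` holds three rows (x, y, z components per volume),
#' `<prefix>.bval` one row of b-values.
#'
#' @param gradients a `nb_gradient_table`.
#' @param prefix output path prefix.
#' @return prefix (write) or `nb_gradient_table` (read).
#' @export
write_bvec_bval <- function(gradients, prefix) {
  utils::write.table(t(gradients$bvecs), paste0(prefix, ".bvec"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(t(gradients$bvals), paste0(prefix, ".bval"),
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_bvec_bval
#' @export
read_bvec_bval <- function(prefix) {
  bvec <- as.matrix(utils::read.table(paste0(prefix, ".bvec")))
  bval <- as.numeric(utils::read.table(paste0(prefix, ".bval"))[1, ])
  if (nrow(bvec) != 3L) stop("parse error in ", prefix, ".bvec: expected 3 rows")
  if (ncol(bvec) != length(bval))
    stop("parse error: bvec/bval volume count mismatch at ", prefix)
  w <- bval > 0
  gt <- gradient_table(t(bvec[, w, drop = FALSE]),
                       b_value = bval[w][1], n_b0 = sum(!w))
  gt$bvals <- bval
  gt$bvecs <- unname(t(bvec))
  gt
}

#' Serialize a seed as JSON
#' @param seed a `nb_seed`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_seed_json <- function(seed, path) {
  jsonlite::write_json(list(center_mm = seed$center_mm,
                            radius_mm = seed$radius_mm,
                            center_vox = seed$center_vox,
                            voxels = seed$voxels),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write a cluster table as TSV
#' @param clusters a `nb_cluster_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(clusters, path) {
  utils::write.table(as.data.frame(clusters), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
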