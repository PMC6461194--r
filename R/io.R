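#' Read and write pipeline files
#'
#' Plain-text interchange used throughout the pipeline: time series as TSV
#' with a header row of node ids (one row per timepoint); square
#' connectivity/adjacency matrices as TSV with node-id header row and
#' first column; partitions as two-column TSV `(node_id, module_id)` with
#' 1-based module labels.
#'
#' @param x matrix (time series or square matrix) or partition vector.
#' @param path file path.
#' @name fcmod_io
NULL

#' @rdname fcmod_io
#' @export
write_timeseries_tsv <- function(x, path) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("n", seq_len(ncol(x)))
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname fcmod_io
#' @export
read_timeseries_tsv <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE))
}

#' @rdname fcmod_io
#' @export
write_matrix_tsv <- function(x, path) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) dimnames(x) <- rep(list(paste0("n", seq_len(ncol(x)))), 2)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname fcmod_io
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}

#' @rdname fcmod_io
#' @export
write_partition_tsv <- function(x, path) {
  memb <- if (inherits(x, "module_partition")) x$assignment else x
  ids <- names(memb)
  if (is.null(ids)) ids <- paste0("n", seq_along(memb))
  utils::write.table(data.frame(node_id = ids, module_id = as.integer(memb)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname fcmod_io
#' @export
read_partition_tsv <- function(path) {
  d <- utils::read.delim(path)
  stats::setNames(as.integer(d$module_id), d$node_id)
}
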