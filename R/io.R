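#' Write / read a recording container
#'
#' Recordings are stored as a single serialized R container (RDS) holding the
#' sample matrix, sampling frequency, recalibration timestamps, channel ids
#' and metadata. The round trip is lossless; on read, the container is
#' validated field by field and a missing or invalid field is reported by
#' name.
#'
#' @param rec an [recording()].
#' @param path file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the validated [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "mea_recording"))
  saveRDS(unclass(rec), path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  for (field in c("samples", "fs", "recalib_timestamps"))
    if (is.null(obj[[field]]))
      stop("recording container is missing `", field, "`")
  if (!is.numeric(obj$fs) || length(obj$fs) != 1 || obj$fs <= 0)
    stop("invalid `fs` in recording container: must be a single value > 0")
  recording(obj$samples, obj$fs, obj$recalib_timestamps,
            obj$channel_ids, if (is.null(obj$metadata)) list() else obj$metadata)
}

#' Write / read a TPM expression matrix as TSV
#'
#' The matrix is written genes x samples with a header row of sample ids and
#' gene ids in the first column (`gene_id`); the sample-to-group map goes to a
#' two-column CSV (`sample`, `group`).
#'
#' @param em an [expression_matrix()].
#' @param path TSV path for the matrix.
#' @param groups_path CSV path for the group map; defaults to
#'   `<path>.groups.csv`.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns the [expression_matrix()].
#' @export
write_expression_tsv <- function(em, path,
                                 groups_path = paste0(path, ".groups.csv")) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene_id = rownames(em$tpm), em$tpm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(sample = names(em$groups), group = em$groups),
                   groups_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path,
                                groups_path = paste0(path, ".groups.csv")) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("expected first column `gene_id`")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  g <- utils::read.csv(groups_path)
  expression_matrix(m, stats::setNames(g$group, g$sample))
}
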