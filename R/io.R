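# Readers/writers for the on-disk formats: TSV tables with comment headers,
# full-precision matrices, and JSON reports.

#' Write a data frame as TSV with optional comment header
#'
#' @param df data frame.
#' @param path output path.
#' @param comments character vector written as leading `# ` lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' Ragged or truncated files raise a parse error naming the offending
#' line.
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                            quote = "")
  nf <- nf[!is.na(nf)]
  if (length(nf) && length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("%s: malformed TSV at data line %d (%d fields, expected %d)",
                 path, bad, nf[bad], nf[1]))
  }
  utils::read.delim(path, comment.char = "#", check.names = FALSE)
}

# Full-precision numeric matrix serialization (lossless round trip).
write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(vapply(seq_len(nrow(m)), function(i)
    paste(sprintf("%.17g", m[i, ]), collapse = "\t"), character(1)), con)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write an epoch set to disk
#'
#' Produces `<prefix>_data.tsv` (full-precision trials x time matrix),
#' `<prefix>_missing.tsv`, `<prefix>_labels.tsv` and `<prefix>_meta.json`
#' (time axis, rate, rejection flags).
#'
#' @param epochs an `epoch_set`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_epoch_set <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "epoch_set"))
  write_matrix_tsv(epochs$data, paste0(prefix, "_data.tsv"))
  write_matrix_tsv(epochs$missing * 1, paste0(prefix, "_missing.tsv"))
  write_tsv(epochs$labels, paste0(prefix, "_labels.tsv"))
  jsonlite::write_json(
    list(time = epochs$time, rate = epochs$rate,
         rejected = epochs$rejected, reject_reason = epochs$reject_reason),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read an epoch set written by [write_epoch_set()]
#'
#' @param prefix path prefix used when writing.
#' @return an `epoch_set`.
#' @export
read_epoch_set <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  structure(list(data = read_matrix_tsv(paste0(prefix, "_data.tsv")),
                 missing = read_matrix_tsv(paste0(prefix,
                                                  "_missing.tsv")) > 0,
                 time = meta$time, rate = meta$rate,
                 labels = read_tsv(paste0(prefix, "_labels.tsv")),
                 rejected = meta$rejected,
                 reject_reason = as.character(meta$reject_reason)),
            class = "epoch_set")
}

#' Write a CBPT cluster report as JSON
#'
#' @param result a `cbpt_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(result, path) {
  stopifnot(inherits(result, "cbpt_result"))
  jsonlite::write_json(
    list(clusters = result$clusters, threshold = result$threshold,
         n = result$n, n_perm = result$n_perm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CBPT cluster report
#'
#' @param path JSON path written by [write_cluster_report()].
#' @return list with `clusters`, `threshold`, `n`, `n_perm`.
#' @export
read_cluster_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
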