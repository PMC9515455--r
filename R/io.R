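# Plain-text IO: FASTA via Biostrings, TSV tables with a stage/parameter
# header comment so every output declares how it was produced.

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences (or DNAStringSet).
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a table as TSV with a provenance header comment
#'
#' The first line is `# stage=<stage> params=<hash>` so downstream readers
#' and audits can tell which pipeline stage and parameter set produced the
#' file.
#'
#' @param df data.frame to write.
#' @param path Output file.
#' @param stage Generating stage name.
#' @param params_hash Parameter-set hash (see [config_hash()]).
#' @export
write_stage_tsv <- function(df, path, stage = "manual", params_hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s params=%s", stage, params_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_stage_tsv()]
#'
#' @param path Input file.
#' @export
read_stage_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a samples x features matrix as TSV
#'
#' Samples as rows, features as columns, first column `sample_id`; the
#' aggregation level is recorded in the header comment.
#'
#' @param mat Matrix with dimnames.
#' @param path File path.
#' @param stage,params_hash Provenance fields.
#' @export
write_matrix_tsv <- function(mat, path, stage = "manual", params_hash = "") {
  df <- data.frame(sample_id = rownames(mat), unclass(mat),
                   check.names = FALSE)
  level <- attr(mat, "level_tag") %||% "matrix"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s params=%s level=%s", stage, params_hash,
                     level), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
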