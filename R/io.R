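# Readers and writers for the package's plain-text formats: expression
# and annotation TSVs, ranked-list TSVs, gene-set files (one tab-separated
# set per line), plain gene lists and GMT collections.

#' Read / write an expression matrix TSV
#'
#' First column holds the gene symbol, the header row the sample IDs.
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate gene symbols in ", path)
  if (anyNA(m)) stop("missing values in ", path)
  m
}

#' @rdname read_expression
#' @param expr Numeric matrix, genes x samples.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read / write a sample annotation TSV
#'
#' Columns: `sample_id`, `class_label`, `subject_id`, `stratum`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class_label", "subject_id", "stratum")
  if (!all(need %in% names(df))) {
    stop("annotation must contain: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_annotation
#' @param annotation Data frame.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read / write gene-set files
#'
#' One gene set per line, tab-separated symbols.
#'
#' @param path File path.
#' @return List of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
}

#' @rdname read_gene_sets
#' @param gene_sets List of character vectors.
#' @export
write_gene_sets <- function(gene_sets, path) {
  writeLines(vapply(gene_sets, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines)]
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, then the member symbols.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "")
  out
}

#' Read / write a ranked list TSV (`gene`, `score`, `rank`)
#'
#' @param path File path.
#' @return A `ranked_list` data frame.
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "score", "rank") %in% names(df)))
  class(df) <- c("ranked_list", "data.frame")
  df
}

#' @rdname read_ranked_list
#' @param ranking A `ranked_list` data frame.
#' @export
write_ranked_list <- function(ranking, path) {
  utils::write.table(ranking, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
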