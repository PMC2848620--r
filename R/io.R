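#' Read a regional expression matrix from a tab-delimited file
#'
#' Expects one gene (probeset) per row: the first column holds gene ids, the
#' header row subject ids, and the body numeric log2 intensities. Duplicate
#' identifiers, missing cells and non-numeric cells are format errors — the
#' analysis requires complete data and refuses to guess.
#'
#' @param path path to a tab-delimited text file.
#' @param region region label attached to the matrix.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, region = "") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4L)
    stop("expression file must have a gene id column plus >= 3 subject columns")
  gene_ids <- raw[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "))
  subject_ids <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                 dimnames = list(gene_ids, subject_ids))
  for (j in seq_along(subject_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !nzchar(trimws(col)))
    if (length(bad))
      stop(sprintf("non-numeric or missing value at row %d (gene '%s'), column '%s'",
                   bad[1L], gene_ids[bad[1L]], subject_ids[j]))
    vals[, j] <- num
  }
  expression_matrix(vals, region = region)
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression_matrix()]: the round trip preserves
#' identifiers exactly and values to full double precision.
#'
#' @param x an `expr_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x),
                   format(unclass(x), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject metadata table
#'
#' Accepts comma- or tab-delimited text with (at least) the columns
#' `subject_id`, `group` and `age`; the delimiter is detected from the
#' header line.
#'
#' @param path path to the metadata file.
#' @return a [subject_table()].
#' @export
read_subject_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "group", "age")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata file is missing column(s): ", paste(miss, collapse = ", "))
  subject_table(df[, need])
}

#' Write a subject metadata table
#'
#' @param x a `subject_table`.
#' @param path output file path.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "subject_table"))
  utils::write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-gene results table as tab-delimited text
#'
#' Works for any of the package's per-gene result data frames
#' (synchrony, detrending report, differential results); column order is
#' preserved as produced.
#'
#' @param x a data frame of results.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
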