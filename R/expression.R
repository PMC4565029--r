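#' Read a gene expression matrix from TSV/CSV
#'
#' Expression files are tab-separated (UTF-8, `.` decimal separator) with a
#' mandatory header row of sample identifiers and a first column of gene
#' identifiers.  Values are continuous and assumed to live on a roughly
#' symmetric (e.g. log) scale.  Rows containing any missing value are dropped
#' with a message; duplicated gene rows are collapsed by their mean with a
#' warning.  Identifiers are case-sensitive opaque strings.
#'
#' @param path path to the expression file.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @return numeric matrix (genes x samples) with unique row and column names,
#'   no missing values and at least two samples.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 2L)
    stop("malformed expression file (no sample columns): ", path)
  if (ncol(df) < 3L)
    stop("expression matrix needs at least 2 samples, found ",
         ncol(df) - 1L, " in ", path)
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]))[1L]
      stop("non-numeric value in column '", names(vals)[j], "', row '",
           ids[bad %||% 1L], "' of ", path)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample identifiers in header of ", path)

  incomplete <- rowSums(is.na(m)) > 0L
  if (any(incomplete)) {
    message("read_expression: dropped ", sum(incomplete),
            " row(s) with missing values")
    m <- m[!incomplete, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("no complete expression rows left in ", path)

  if (anyDuplicated(rownames(m))) {
    n_dup <- sum(duplicated(rownames(m)))
    ids <- rownames(m)
    first <- !duplicated(ids)
    collapsed <- rowsum(m, group = ids, reorder = FALSE) /
      as.vector(table(factor(ids, levels = ids[first])))
    m <- collapsed[ids[first], , drop = FALSE]
    warning("read_expression: collapsed ", n_dup,
            " duplicated gene row(s) by mean")
  }
  validate_expression(m)
  m
}

#' Write an expression (or any genes-x-samples) matrix as TSV
#'
#' @param expr numeric matrix with row and column names.
#' @param path output path.
#' @param id_col header for the identifier column (first column).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, id_col = "gene_id", sep = "\t") {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Check ExpressionMatrix invariants; called by readers and entry points.
validate_expression <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must carry gene and sample identifiers")
  if (anyDuplicated(rownames(expr))) stop("duplicated gene identifiers")
  if (anyDuplicated(colnames(expr))) stop("duplicated sample identifiers")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (ncol(expr) < 2L) stop("expression matrix needs at least 2 samples")
  invisible(expr)
}

#' Read a transcription factor list
#'
#' Plain text, one identifier per line; blank lines ignored, duplicates
#' removed.
#'
#' @param path path to the file.
#' @return character vector of TF identifiers.
#' @export
read_tf_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- unique(x[nzchar(x)])
  if (length(x) == 0L) stop("TF list is empty: ", path)
  x
}

# Restrict a TF list to genes present in the matrix, warning about the rest.
match_tfs <- function(tfs, expr) {
  present <- intersect(tfs, rownames(expr))
  absent <- setdiff(tfs, rownames(expr))
  if (length(absent))
    warning("ignoring ", length(absent), " TF(s) absent from the matrix: ",
            paste(utils::head(absent, 5L), collapse = ", "),
            if (length(absent) > 5L) ", ..." else "")
  present
}
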