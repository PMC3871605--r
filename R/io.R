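#' Read and write the pipeline's tabular formats
#'
#' The expression matrix is tab-separated with a header row of sample IDs
#' and gene IDs in the first column; the design and annotation tables are
#' two-column TSVs (`sample`/`condition` and `gene`/`category`).
#'
#' @param path file path.
#' @return `read_expression_matrix()` a numeric matrix with dimnames;
#'   `read_design()` / `read_annotation()` data.frames.
#' @name ruminet_io
NULL

#' @rdname ruminet_io
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (anyDuplicated(genes)) stop("duplicate gene IDs in ", path,
                                 call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite values in ", path, call. = FALSE)
  m
}

#' @rdname ruminet_io
#' @param matrix numeric genes x samples matrix.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ruminet_io
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(df))) {
    stop("design file needs columns 'sample' and 'condition'", call. = FALSE)
  }
  df
}

#' @rdname ruminet_io
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation file needs two columns", call. = FALSE)
  names(df)[1:2] <- c("gene", "category")
  df[, 1:2]
}

#' Read gene/term pairs from a GAF 2.x association file
#'
#' Accepts only the object identifier (column 2) and term (column 5);
#' comment lines starting with `!` are skipped.
#'
#' @param path GAF file path.
#' @return data.frame with columns `gene` and `category`.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 5L
  if (any(bad)) stop("GAF lines with fewer than 5 columns", call. = FALSE)
  unique(data.frame(gene = vapply(parts, `[[`, character(1), 2L),
                    category = vapply(parts, `[[`, character(1), 5L),
                    stringsAsFactors = FALSE))
}
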