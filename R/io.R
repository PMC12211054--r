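#' Read a named numeric matrix from TSV or MatrixMarket files
#'
#' TSV: header row of column names, first column = row names. MTX: a
#' MatrixMarket triplet file with sidecar row/column name files (one name
#' per line).
#'
#' @param path matrix file
#' @param format "tsv" or "mtx" (default: guessed from the extension)
#' @param row_names,col_names for MTX, paths to the name files
#' @return dense numeric matrix with dimnames
#' @export
read_matrix <- function(path, format = NULL, row_names = NULL,
                        col_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
    return(as.matrix(tab))
  }
  m <- as.matrix(Matrix::readMM(path))
  if (!is.null(row_names)) {
    rn <- readLines(row_names, warn = FALSE)
    if (length(rn) != nrow(m)) {
      stop(sprintf("row-name file has %d entries for %d rows", length(rn),
                   nrow(m)))
    }
    rownames(m) <- rn
  }
  if (!is.null(col_names)) {
    cn <- readLines(col_names, warn = FALSE)
    if (length(cn) != ncol(m)) {
      stop(sprintf("column-name file has %d entries for %d columns",
                   length(cn), ncol(m)))
    }
    colnames(m) <- cn
  }
  m
}

#' Write a named numeric matrix as TSV (12 significant digits)
#'
#' Round-trips through [read_matrix()] to within 1e-10 relative error.
#'
#' @param m matrix with dimnames
#' @param path output path
#' @return invisibly, `path`
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(signif(m, 12), check.names = FALSE)
  utils::write.table(cbind(feature = rownames(m), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors
#' @param path output path
#' @return invisibly, `path`
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}
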