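#' Read a mixture matrix from delimited text
#'
#' Reads a TSV (default) or CSV matrix with mixtures in rows and samples in
#' columns. A header row and a first column of row labels are auto-detected
#' (either may be absent); missing labels are generated as `m1..mM` and
#' `s1..sN`. Ragged rows, non-numeric cells, and duplicated labels are
#' errors.
#'
#' @param path File path; `.csv` implies comma separation, anything else
#'   tab.
#' @param sep Field separator overriding the extension-based default.
#' @param transpose Set TRUE when the file stores samples in rows.
#' @return A labelled numeric matrix (M x N).
#' @export
read_mixture_matrix <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("read_mixture_matrix(): no such file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  body <- suppressWarnings(as.numeric(first[-1]))
  has_header <- length(first) > 1 && anyNA(body)
  if (has_header) {
    hdr <- first
    if (hdr[1] == "") hdr <- hdr[-1]
    if (anyDuplicated(hdr)) {
      stop("read_mixture_matrix(): duplicated column labels in ", path)
    }
  }
  df <- utils::read.table(
    path, sep = sep, header = has_header, check.names = FALSE,
    stringsAsFactors = FALSE, comment.char = "", quote = "\""
  )
  row_labels <- NULL
  if (ncol(df) > 0 && !is.numeric(df[[1]])) {
    row_labels <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  X <- as.matrix(df)
  if (!is.numeric(X)) {
    stop("read_mixture_matrix(): non-numeric cells in ", path)
  }
  if (is.null(row_labels)) row_labels <- paste0("m", seq_len(nrow(X)))
  col_labels <- if (has_header) colnames(X) else paste0("s", seq_len(ncol(X)))
  if (anyDuplicated(row_labels)) {
    stop("read_mixture_matrix(): duplicated row labels in ", path)
  }
  if (anyDuplicated(col_labels)) {
    stop("read_mixture_matrix(): duplicated column labels in ", path)
  }
  dimnames(X) <- list(row_labels, col_labels)
  if (transpose) X <- t(X)
  X
}

#' Write a mixture matrix as delimited text
#'
#' Writes the matrix with row and column labels at full double precision so
#' a write/read round trip reproduces the values to within float formatting.
#'
#' @param path Output path; `.csv` implies comma separation, anything else
#'   tab.
#' @param X Numeric matrix; missing dimnames are generated.
#' @param sep Field separator overriding the extension-based default.
#' @return `path`, invisibly.
#' @export
write_mixture_matrix <- function(path, X, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("m", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("s", seq_len(ncol(X)))
  body <- format(X, digits = 17, trim = TRUE, scientific = NA)
  lines <- c(
    paste(c("", colnames(X)), collapse = sep),
    vapply(
      seq_len(nrow(X)),
      function(i) paste(c(rownames(X)[i], body[i, ]), collapse = sep),
      character(1)
    )
  )
  writeLines(lines, path)
  invisible(path)
}
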