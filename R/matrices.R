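#' Labelled square matrices
#'
#' Pairwise quantities in this package (F_ST, over-water distance, dispersal
#' probability and flow) are square matrices whose rows and columns are site
#' or patch names.  These helpers move between the matrix form and a tidy
#' long tibble, and read/write the CSV layout used throughout: a header row
#' of labels and a leading label column.
#'
#' @param x for [as_labelled_matrix()], a square numeric matrix with
#'   dimnames, or a data frame whose first column holds the row labels and
#'   whose remaining columns are numeric; for [matrix_to_tibble()], a
#'   labelled matrix.
#' @param path file path for reading or writing.
#' @param diagonal if `FALSE` (default) the diagonal is dropped from the
#'   long form.
#' @return `as_labelled_matrix()` and `read_matrix_csv()` return a named
#'   square matrix; `matrix_to_tibble()` returns a tibble with columns
#'   `from`, `to`, `value`; `write_matrix_csv()` returns `path` invisibly.
#' @examples
#' m <- as_labelled_matrix(matrix(c(0, 1, 1, 0), 2,
#'   dimnames = list(c("a", "b"), c("a", "b"))))
#' matrix_to_tibble(m)
#' @export
as_labelled_matrix <- function(x) {
  if (is.data.frame(x)) {
    labels <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- labels
    x <- m
  }
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    stop("`x` must be a square matrix or a data frame with a label column.",
         call. = FALSE)
  }
  if (is.null(rownames(x))) stop("matrix must carry row labels.", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- rownames(x)
  if (!identical(rownames(x), colnames(x))) {
    x <- x[, rownames(x), drop = FALSE]
  }
  x
}

#' @rdname as_labelled_matrix
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as_labelled_matrix(df)
}

#' @rdname as_labelled_matrix
#' @export
write_matrix_csv <- function(x, path) {
  x <- as_labelled_matrix(x)
  df <- data.frame(site = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname as_labelled_matrix
#' @export
matrix_to_tibble <- function(x, diagonal = FALSE) {
  x <- as_labelled_matrix(x)
  out <- tibble::tibble(
    from = rep(rownames(x), times = ncol(x)),
    to = rep(colnames(x), each = nrow(x)),
    value = as.vector(x)
  )
  if (!diagonal) out <- dplyr::filter(out, .data$from != .data$to)
  out
}

# Check symmetry with a tolerance; used by mantel and network builders.
check_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (max(abs(m - t(m))) > tol) {
    stop("`", name, "` must be symmetric.", call. = FALSE)
  }
  invisible(m)
}

# Align B's labels to A's, erroring on mismatch.
align_labels <- function(a, b) {
  if (!setequal(rownames(a), rownames(b))) {
    stop("matrices do not share the same labels.", call. = FALSE)
  }
  b[rownames(a), rownames(a)]
}
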