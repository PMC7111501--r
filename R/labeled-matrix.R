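#' Labeled numeric matrix
#'
#' The central data container: a numeric matrix together with ordered row and
#' column label vectors. Labels are kept outside the matrix `dimnames` because
#' uploaded matrices may legitimately carry duplicate labels until
#' [dedupe_labels()] is applied. Missing cells are `NA`; every non-missing cell
#' is a finite double. The number of *invalid* cells seen at parse time (tokens
#' that were neither numeric nor a recognized missing token) travels with the
#' object in `n_invalid`.
#'
#' @param values numeric matrix (or something coercible); non-finite entries
#'   are converted to `NA`.
#' @param row_labels,col_labels character vectors of axis labels; default to
#'   the matrix `dimnames` or `R1..`, `C1..`.
#' @param n_invalid count of invalid cells observed when the matrix was parsed.
#' @return an object of class `labeled_matrix` with fields `values`,
#'   `row_labels`, `col_labels`, `n_invalid`.
#' @examples
#' m <- labeled_matrix(matrix(1:6, 2, 3), c("g1", "g2"), c("s1", "s2", "s3"))
#' dim(m)
#' @export
labeled_matrix <- function(values, row_labels = NULL, col_labels = NULL,
                           n_invalid = 0L) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  values[!is.finite(values)] <- NA_real_
  if (is.null(row_labels)) {
    row_labels <- rownames(values)
    if (is.null(row_labels)) row_labels <- paste0("R", seq_len(nrow(values)))
  }
  if (is.null(col_labels)) {
    col_labels <- colnames(values)
    if (is.null(col_labels)) col_labels <- paste0("C", seq_len(ncol(values)))
  }
  row_labels <- as.character(row_labels)
  col_labels <- as.character(col_labels)
  if (length(row_labels) != nrow(values))
    stop("row_labels length (", length(row_labels), ") != nrow (", nrow(values), ")")
  if (length(col_labels) != ncol(values))
    stop("col_labels length (", length(col_labels), ") != ncol (", ncol(values), ")")
  dimnames(values) <- NULL
  structure(
    list(values = values, row_labels = row_labels, col_labels = col_labels,
         n_invalid = as.integer(n_invalid)),
    class = "labeled_matrix"
  )
}

#' @export
dim.labeled_matrix <- function(x) dim(x$values)

#' Number of rows / columns of a labeled matrix
#' @param m a [labeled_matrix()].
#' @return integer count.
#' @export
n_rows <- function(m) nrow(m$values)

#' @rdname n_rows
#' @export
n_cols <- function(m) ncol(m$values)

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("<labeled_matrix> %d x %d, %d missing cell(s), %d invalid at parse\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)), x$n_invalid))
  k <- min(5L, nrow(x$values)); j <- min(5L, ncol(x$values))
  if (k > 0 && j > 0) {
    v <- x$values[seq_len(k), seq_len(j), drop = FALSE]
    dimnames(v) <- list(x$row_labels[seq_len(k)], x$col_labels[seq_len(j)])
    print(v)
    if (nrow(x$values) > k || ncol(x$values) > j) cat("...\n")
  }
  invisible(x)
}

is_labeled_matrix <- function(x) inherits(x, "labeled_matrix")

stopifnot_lm <- function(m) {
  if (!is_labeled_matrix(m)) stop("expected a labeled_matrix")
  invisible(m)
}

#' Test two labeled matrices for cell-for-cell equality
#'
#' Labels must be identical and every cell equal (NA pattern included), within
#' `tol` for non-missing values.
#' @param a,b labeled matrices.
#' @param tol absolute tolerance on cell values.
#' @return logical scalar.
#' @export
lm_equal <- function(a, b, tol = 0) {
  if (!identical(dim(a$values), dim(b$values))) return(FALSE)
  if (!identical(a$row_labels, b$row_labels)) return(FALSE)
  if (!identical(a$col_labels, b$col_labels)) return(FALSE)
  na_a <- is.na(a$values); na_b <- is.na(b$values)
  if (!identical(na_a, na_b)) return(FALSE)
  if (any(!na_a)) {
    d <- abs(a$values[!na_a] - b$values[!na_b])
    if (tol == 0) return(all(a$values[!na_a] == b$values[!na_b]))
    return(all(d <= tol))
  }
  TRUE
}

# axis helpers: "row" vectors are matrix rows, "col" vectors are matrix columns
check_axis <- function(axis) {
  if (!is.character(axis) || length(axis) != 1 || !axis %in% c("row", "col"))
    stop("axis must be \"row\" or \"col\"")
  axis
}

axis_labels <- function(m, axis) {
  if (check_axis(axis) == "row") m$row_labels else m$col_labels
}

# matrix whose rows are the vectors along `axis`
axis_vectors <- function(m, axis) {
  if (check_axis(axis) == "row") m$values else t(m$values)
}
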