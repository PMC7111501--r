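#' Region specification for matrix parsing
#'
#' Identifies, with 0-based indices, which row of the uploaded grid holds the
#' column labels, which column holds the row labels, and where the numeric data
#' region starts. The default region assumes labels in row 0 / column 0 and
#' data starting at (1, 1).
#'
#' @param label_row 0-based row index of the column-label row.
#' @param label_col 0-based column index of the row-label column.
#' @param data_origin 0-based `(row, col)` of the top-left data cell; must be
#'   strictly below `label_row` and strictly right of `label_col`.
#' @return a `region_spec` object.
#' @export
region_spec <- function(label_row = 0L, label_col = 0L,
                        data_origin = c(label_row + 1L, label_col + 1L)) {
  label_row <- as.integer(label_row); label_col <- as.integer(label_col)
  data_origin <- as.integer(data_origin)
  if (length(data_origin) != 2) stop("data_origin must be (row, col)")
  if (data_origin[1] <= label_row)
    stop("data_origin row must lie strictly below the label row")
  if (data_origin[2] <= label_col)
    stop("data_origin col must lie strictly right of the label column")
  structure(list(label_row = label_row, label_col = label_col,
                 data_origin = data_origin),
            class = "region_spec")
}

# Missing tokens accepted on input (case-insensitive). Anything else that does
# not parse as a finite number is "invalid": it becomes missing but is counted.
MISSING_TOKENS <- c("", "na", "nan", "null")

read_raw_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("txt", "tsv", "csv")) {
    sep <- if (ext == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = FALSE, sep = sep, quote = "\"",
                        colClasses = "character", comment.char = "",
                        check.names = FALSE, fill = TRUE,
                        na.strings = character(), blank.lines.skip = FALSE,
                        stringsAsFactors = FALSE),
      error = function(e) stop("cannot read '", path, "': ", conditionMessage(e))
    )
    as.matrix(df)
  } else if (ext == "xlsx") {
    # first worksheet only; formula cells yield their cached value
    df <- tryCatch(
      readxl::read_xlsx(path, sheet = 1, col_names = FALSE, col_types = "text",
                        .name_repair = "minimal"),
      error = function(e) stop("cannot read '", path, "': ", conditionMessage(e))
    )
    g <- as.matrix(df)
    g[is.na(g)] <- ""
    g
  } else {
    stop("unsupported matrix format '.", ext, "' (accepted: .txt, .csv, .xlsx)")
  }
}

# character tokens -> doubles + invalid count; recognized missing tokens are
# missing, all other unparseable (or non-finite) tokens are invalid
parse_tokens <- function(tok) {
  tok <- trimws(tok)
  miss <- tolower(tok) %in% MISSING_TOKENS
  v <- suppressWarnings(as.numeric(tok))
  invalid <- !miss & !is.finite(v)
  v[miss | invalid] <- NA_real_
  list(values = v, n_invalid = sum(invalid))
}

grid_to_matrix <- function(grid, region) {
  nr <- nrow(grid); nc <- ncol(grid)
  r0 <- region$data_origin[1] + 1L  # 1-based
  c0 <- region$data_origin[2] + 1L
  # a grid ending exactly at the label row yields a valid 0-row matrix
  if (r0 > nr + 1L || c0 > nc) stop("empty data region: data origin outside the grid")
  col_labels <- trimws(grid[region$label_row + 1L, c0:nc])
  if (r0 > nr) {
    return(labeled_matrix(matrix(numeric(0), 0L, nc - c0 + 1L),
                          character(0), col_labels))
  }
  row_labels <- trimws(grid[r0:nr, region$label_col + 1L])
  p <- parse_tokens(grid[r0:nr, c0:nc, drop = FALSE])
  values <- matrix(p$values, nrow = nr - r0 + 1L, ncol = nc - c0 + 1L)
  labeled_matrix(values, row_labels, col_labels, n_invalid = p$n_invalid)
}

#' Parse a matrix file into a labeled matrix
#'
#' Accepts tab-delimited text (`.txt`), comma-separated text (`.csv`,
#' RFC-4180 quoting) and Excel spreadsheets (`.xlsx`, first worksheet). The
#' same logical table parses to an identical [labeled_matrix()] in all three
#' dialects. Non-numeric data cells become missing; tokens other than the
#' recognized missing set (`""`, `NA`, `NaN`, `null`, case-insensitive) are
#' counted in `n_invalid`.
#'
#' @param path matrix file.
#' @param region a [region_spec()]; defaults to labels in row 0 / column 0.
#' @return a [labeled_matrix()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,s1,s2", "g1,1.0,2.0", "g2,3.0,4.0"), f)
#' parse_matrix(f)
#' @export
parse_matrix <- function(path, region = NULL) {
  if (is.null(region)) region <- region_spec()
  grid <- read_raw_grid(path)
  m <- grid_to_matrix(grid, region)
  if (n_cols(m) == 0) stop("empty data region in '", path, "'")
  m
}

#' Disambiguate duplicate axis labels
#'
#' The first occurrence of a label is kept; occurrence `k` (2-based) becomes
#' `<label>_<k>`, incrementing `k` further if the suffixed name collides with
#' an existing label. Keeping the first occurrence untouched means covariate
#' files keyed on the original label still match. Idempotent on unique labels.
#'
#' @param m a [labeled_matrix()].
#' @param axis `"row"` or `"col"`.
#' @param mode only `"rename"` is supported.
#' @return the matrix with unique labels on `axis`.
#' @export
dedupe_labels <- function(m, axis, mode = "rename") {
  stopifnot_lm(m); check_axis(axis)
  if (!identical(mode, "rename")) stop("unsupported dedupe mode '", mode, "'")
  labs <- axis_labels(m, axis)
  out <- make_unique_labels(labs)
  if (axis == "row") m$row_labels <- out else m$col_labels <- out
  m
}

make_unique_labels <- function(labs) {
  seen <- new.env(parent = emptyenv())
  out <- character(length(labs))
  all_set <- new.env(parent = emptyenv())
  for (i in seq_along(labs)) {
    lab <- labs[i]
    cnt <- if (is.null(seen[[lab]])) 0L else seen[[lab]]
    if (cnt == 0L) {
      cand <- lab
    } else {
      k <- cnt + 1L
      cand <- paste0(lab, "_", k)
      # avoid colliding with already-assigned names or any label in the input
      while (!is.null(all_set[[cand]]) || cand %in% labs) {
        k <- k + 1L
        cand <- paste0(lab, "_", k)
      }
    }
    seen[[lab]] <- cnt + 1L
    all_set[[cand]] <- TRUE
    out[i] <- cand
  }
  out
}

# shortest decimal representation that round-trips to the same double
format_roundtrip <- function(x) {
  out <- sprintf("%.15g", x)
  bad <- suppressWarnings(as.numeric(out)) != x
  bad[is.na(bad)] <- FALSE
  if (any(bad)) out[bad] <- sprintf("%.17g", x[bad])
  out[is.na(x)] <- "NA"
  out
}

#' Write a labeled matrix as tab-delimited text
#'
#' Column labels form the header row (with an empty leading field), row labels
#' the first column; missing cells are written as `NA`. Values are written with
#' enough digits that [parse_matrix()] on the output reproduces the matrix
#' exactly, cell for cell.
#'
#' @param m a [labeled_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot_lm(m)
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    stop("cannot write '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  header <- paste(c("", m$col_labels), collapse = "\t")
  lines <- header
  if (n_rows(m) > 0) {
    body <- matrix(format_roundtrip(m$values), nrow = n_rows(m))
    rows <- apply(cbind(m$row_labels, body), 1L, paste, collapse = "\t")
    lines <- c(lines, rows)
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
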