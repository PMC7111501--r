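#' Covariate bar
#'
#' Per-label annotation attached to one axis of the heat map, either discrete
#' (categorical strings) or continuous (numbers). Values are stored as a named
#' vector keyed by axis label; labels without a value are missing and drawn in
#' the dedicated missing color. Colors are attached by [default_colors()] (or
#' set manually) and the `position` field orders bars on their axis.
#'
#' @param name covariate name (e.g. `"smoking status"`).
#' @param axis `"row"` or `"col"`.
#' @param kind `"discrete"` or `"continuous"`.
#' @param values named character (discrete) or named numeric (continuous)
#'   vector keyed by axis label; `NA` marks missing.
#' @param colors for discrete covariates a named vector of hex colors per
#'   category plus a `missing_color` attribute; for continuous a
#'   [color_map()]. Usually left `NULL` and filled by [default_colors()].
#' @param position 1-based ordering index among the bars on this axis.
#' @return a `covariate` object.
#' @export
covariate <- function(name, axis, kind = c("discrete", "continuous"),
                      values, colors = NULL, position = 1L) {
  check_axis(axis)
  kind <- match.arg(kind)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("covariate values must be named by axis label")
  if (kind == "continuous") {
    values <- stats::setNames(as.numeric(values), names(values))
  } else {
    values <- stats::setNames(as.character(values), names(values))
  }
  structure(list(name = name, axis = axis, kind = kind, values = values,
                 colors = colors, position = as.integer(position)),
            class = "covariate")
}

#' @export
print.covariate <- function(x, ...) {
  cat(sprintf("<covariate> '%s' (%s, %s axis): %d value(s), %d missing\n",
              x$name, x$kind, x$axis, length(x$values), sum(is.na(x$values))))
  invisible(x)
}

covariate_categories <- function(cov) {
  # categories in order of first appearance along the axis
  v <- cov$values[!is.na(cov$values)]
  unique(as.character(v))
}

#' Parse a covariate file
#'
#' Covariate files hold one `label<sep>value` pair per line, tab- or
#' comma-delimited (auto-detected from the first line). Entries whose label is
#' not among the matrix labels are dropped with a warning; matrix labels
#' absent from the file get a missing value. For continuous covariates a
#' header line is auto-detected (first line whose second field is not a
#' number) and non-numeric values become missing with a warning.
#'
#' @param path covariate file.
#' @param axis `"row"` or `"col"`.
#' @param kind `"discrete"` or `"continuous"`.
#' @param matrix_labels the matrix's labels on that axis.
#' @param name covariate name; defaults to the file base name.
#' @return a [covariate()] keyed by `matrix_labels` (missing where no value).
#' @export
parse_covariate <- function(path, axis, kind = c("discrete", "continuous"),
                            matrix_labels,
                            name = tools::file_path_sans_ext(basename(path))) {
  check_axis(axis)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read covariate file '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("covariate file '", path, "' is empty")
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 2
  if (all(bad)) stop("covariate file '", path, "' has no two-field lines")
  parts <- parts[!bad]
  keys <- trimws(vapply(parts, `[[`, "", 1L))
  vals <- trimws(vapply(parts, `[[`, "", 2L))
  if (kind == "continuous" && length(keys) > 1) {
    # header auto-detection: first line whose second field is non-numeric
    if (is.na(suppressWarnings(as.numeric(vals[1]))) &&
        !tolower(vals[1]) %in% MISSING_TOKENS) {
      keys <- keys[-1]; vals <- vals[-1]
    }
  }
  unmatched <- setdiff(keys, matrix_labels)
  if (length(unmatched))
    warning(length(unmatched), " covariate label(s) not in the matrix, dropped: ",
            paste(utils::head(unmatched, 5), collapse = ", "),
            if (length(unmatched) > 5) ", ..." else "")
  keep <- keys %in% matrix_labels
  keys <- keys[keep]; vals <- vals[keep]
  if (anyDuplicated(keys)) {
    warning("duplicate labels in covariate file; last value wins")
    last <- !duplicated(keys, fromLast = TRUE)
    keys <- keys[last]; vals <- vals[last]
  }
  if (kind == "continuous") {
    miss <- tolower(vals) %in% MISSING_TOKENS
    num <- suppressWarnings(as.numeric(vals))
    nonnum <- !miss & is.na(num)
    if (any(nonnum))
      warning(sum(nonnum), " non-numeric value(s) in continuous covariate set to missing")
    full <- stats::setNames(rep(NA_real_, length(matrix_labels)), matrix_labels)
    full[keys] <- num
  } else {
    vals[tolower(vals) %in% MISSING_TOKENS] <- NA_character_
    full <- stats::setNames(rep(NA_character_, length(matrix_labels)), matrix_labels)
    full[keys] <- vals
  }
  covariate(name = name, axis = axis, kind = kind, values = full)
}

#' Named color palette
#'
#' @param name palette name.
#' @param colors ordered vector of 6-digit hex colors (`#RRGGBB`).
#' @return a `chm_palette`.
#' @export
chm_palette <- function(name, colors) {
  colors <- toupper(as.character(colors))
  if (length(colors) == 0) stop("palette must have at least one color")
  if (!all(grepl("^#[0-9A-F]{6}$", colors)))
    stop("palette colors must be 6-digit hex (#RRGGBB)")
  structure(list(name = name, colors = colors), class = "chm_palette")
}

#' Colorblind-safe default palette (Okabe-Ito)
#' @return a `chm_palette` of 8 colors.
#' @export
default_palette <- function() {
  chm_palette("okabe-ito",
              c("#E69F00", "#56B4E9", "#009E73", "#F0E442",
                "#0072B2", "#D55E00", "#CC79A7", "#000000"))
}

#' Assign default colors to a covariate
#'
#' Discrete: categories get palette colors cyclically, in order of first
#' appearance along the axis; missing entries get a dedicated missing color
#' (default white), distinct from category colors. Continuous: a two-point
#' [color_map()] spanning the observed min..max, ramping from white to the
#' palette's first color. Deterministic: the same covariate and palette always
#' give the same assignment.
#'
#' @param cov a [covariate()].
#' @param pal a `chm_palette` (default [default_palette()]).
#' @param missing_color hex color for missing entries.
#' @return the covariate with its `colors` field populated.
#' @export
default_colors <- function(cov, pal = default_palette(),
                           missing_color = "#FFFFFF") {
  if (!inherits(cov, "covariate")) stop("expected a covariate")
  if (!inherits(pal, "chm_palette")) stop("expected a chm_palette")
  if (cov$kind == "discrete") {
    cats <- covariate_categories(cov)
    cols <- pal$colors[((seq_along(cats) - 1L) %% length(pal$colors)) + 1L]
    colors <- stats::setNames(cols, cats)
    attr(colors, "missing_color") <- toupper(missing_color)
    cov$colors <- colors
  } else {
    v <- cov$values[is.finite(cov$values)]
    if (length(v) == 0) {
      lo <- 0; hi <- 1
    } else {
      lo <- min(v); hi <- max(v)
      if (lo == hi) hi <- lo + 1   # degenerate span: widen to keep breakpoints strict
    }
    cov$colors <- color_map(c(lo, hi), c("#FFFFFF", pal$colors[1]),
                            missing_color = missing_color)
  }
  cov
}

#' Reorder covariate bars
#'
#' @param bars list of [covariate()] on one axis.
#' @param order permutation of `seq_along(bars)`; `order[1]` names the bar to
#'   draw first (closest to the matrix body).
#' @return the reordered list with `position` fields renumbered `1..n`.
#' @export
reorder_bars <- function(bars, order) {
  n <- length(bars)
  order <- as.integer(order)
  if (length(order) != n || anyNA(order) || !setequal(order, seq_len(n)) ||
      anyDuplicated(order))
    stop("order must be a permutation of 1..", n)
  out <- bars[order]
  for (i in seq_along(out)) out[[i]]$position <- i
  out
}

#' Lift embedded covariate rows/columns out of an uploaded grid
#'
#' Uploaded matrices may carry classification data inside the file: extra
#' rows between the column-label row and the data region become column
#' covariates, and extra columns between the row-label column and the data
#' region become row covariates. The kind is auto-proposed (all values
#' numeric -> continuous, else discrete) but can be overridden downstream.
#'
#' @param path matrix file (any accepted dialect).
#' @param covariate_rows 0-based grid row indices to lift as column covariates.
#' @param covariate_cols 0-based grid column indices to lift as row covariates.
#' @param region a [region_spec()] whose `data_origin` lies beyond the lifted
#'   rows/columns.
#' @return list with `matrix` (a [labeled_matrix()]) and `covariates`
#'   (list of [covariate()]).
#' @export
extract_embedded_covariates <- function(path, covariate_rows = integer(0),
                                        covariate_cols = integer(0),
                                        region = NULL) {
  grid <- read_raw_grid(path)
  if (is.null(region)) {
    region <- region_spec(
      data_origin = c(1L + length(covariate_rows), 1L + length(covariate_cols)))
  }
  covariate_rows <- as.integer(covariate_rows)
  covariate_cols <- as.integer(covariate_cols)
  for (r in covariate_rows)
    if (r <= region$label_row || r >= region$data_origin[1])
      stop("covariate row ", r, " must lie between the label row and the data region")
  for (cc in covariate_cols)
    if (cc <= region$label_col || cc >= region$data_origin[2])
      stop("covariate column ", cc, " must lie between the label column and the data region")
  m <- grid_to_matrix(grid, region)
  covs <- list()
  for (r in covariate_rows) {
    vals <- trimws(grid[r + 1L, (region$data_origin[2] + 1L):ncol(grid)])
    nm <- trimws(grid[r + 1L, region$label_col + 1L])
    if (!nzchar(nm)) nm <- paste0("covariate_row_", r)
    covs <- c(covs, list(make_embedded_cov(nm, "col", vals, m$col_labels)))
  }
  for (cc in covariate_cols) {
    vals <- trimws(grid[(region$data_origin[1] + 1L):nrow(grid), cc + 1L])
    nm <- trimws(grid[region$label_row + 1L, cc + 1L])
    if (!nzchar(nm)) nm <- paste0("covariate_col_", cc)
    covs <- c(covs, list(make_embedded_cov(nm, "row", vals, m$row_labels)))
  }
  for (i in seq_along(covs)) covs[[i]]$position <- i
  list(matrix = m, covariates = covs)
}

make_embedded_cov <- function(name, axis, vals, labels) {
  miss <- tolower(vals) %in% MISSING_TOKENS
  num <- suppressWarnings(as.numeric(vals))
  all_numeric <- all(miss | !is.na(num))
  if (all_numeric) {
    num[miss] <- NA_real_
    covariate(name, axis, "continuous", stats::setNames(num, labels))
  } else {
    v <- vals; v[miss] <- NA_character_
    covariate(name, axis, "discrete", stats::setNames(v, labels))
  }
}

#' Local palette store
#'
#' Palettes are kept in a local JSON document mapping palette name to its
#' color list. A missing store is created on first use, seeded with the
#' colorblind-safe default palette.
#'
#' @param store_path path of the JSON palette store.
#' @param pal a `chm_palette` to save.
#' @return `save_palette`/`init_palette_store`: the store path invisibly;
#'   `load_palette`: a `chm_palette`; `list_palettes`: character vector of
#'   names.
#' @export
init_palette_store <- function(store_path) {
  if (!file.exists(store_path)) {
    dp <- default_palette()
    pals <- stats::setNames(list(dp$colors), dp$name)
    jsonlite::write_json(pals, store_path, pretty = TRUE)
  }
  invisible(store_path)
}

#' @rdname init_palette_store
#' @export
save_palette <- function(store_path, pal) {
  if (!inherits(pal, "chm_palette")) stop("expected a chm_palette")
  init_palette_store(store_path)
  pals <- jsonlite::read_json(store_path, simplifyVector = TRUE)
  pals[[pal$name]] <- pal$colors
  jsonlite::write_json(pals[order(names(pals))], store_path, pretty = TRUE)
  invisible(store_path)
}

#' @rdname init_palette_store
#' @param name palette name to load.
#' @export
load_palette <- function(store_path, name) {
  init_palette_store(store_path)
  pals <- jsonlite::read_json(store_path, simplifyVector = TRUE)
  if (is.null(pals[[name]])) stop("no palette named '", name, "' in store")
  chm_palette(name, pals[[name]])
}

#' @rdname init_palette_store
#' @export
list_palettes <- function(store_path) {
  init_palette_store(store_path)
  names(jsonlite::read_json(store_path, simplifyVector = TRUE))
}
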