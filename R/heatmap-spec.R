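#' Breakpoint color map
#'
#' Maps numbers to colors through a strictly increasing breakpoint sequence:
#' each breakpoint is pinned to a color, values between breakpoints are
#' channel-wise linearly interpolated, values outside the span are clamped to
#' the end colors, and missing values take the dedicated missing color.
#'
#' @param breakpoints strictly increasing numeric vector, length >= 2.
#' @param colors one `#RRGGBB` color per breakpoint.
#' @param missing_color hex color for missing cells.
#' @return a `color_map`.
#' @export
color_map <- function(breakpoints, colors, missing_color = "#CCCCCC") {
  breakpoints <- as.numeric(breakpoints)
  colors <- toupper(as.character(colors))
  missing_color <- toupper(missing_color)
  if (length(breakpoints) < 2) stop("need at least 2 breakpoints")
  if (length(breakpoints) != length(colors))
    stop("breakpoints and colors must have equal length")
  if (any(diff(breakpoints) <= 0)) stop("breakpoints must be strictly increasing")
  if (!all(grepl("^#[0-9A-F]{6}$", c(colors, missing_color))))
    stop("colors must be 6-digit hex (#RRGGBB)")
  structure(list(breakpoints = breakpoints, colors = colors,
                 missing_color = missing_color),
            class = "color_map")
}

#' @export
print.color_map <- function(x, ...) {
  cat("<color_map>", paste(sprintf("%g=%s", x$breakpoints, x$colors),
                           collapse = " "),
      "missing:", x$missing_color, "\n")
  invisible(x)
}

hex_to_rgb <- function(hex) t(grDevices::col2rgb(hex))

rgb_to_hex <- function(rgb) {
  toupper(grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255))
}

#' Map values to colors
#'
#' Vectorized. `NA` maps to the missing color; values at or beyond the end
#' breakpoints clamp to the end colors; values at a breakpoint return exactly
#' that breakpoint's color; in between, each RGB channel is interpolated
#' linearly (rounded to the nearest integer channel value).
#'
#' @param cm a [color_map()].
#' @param v numeric vector (may contain `NA`).
#' @return character vector of `#RRGGBB` colors.
#' @examples
#' cm <- color_map(c(-2, 0, 2), c("#0000FF", "#FFFFFF", "#FF0000"))
#' map_color(cm, c(-5, 0, 1, NA))
#' @export
map_color <- function(cm, v) {
  if (!inherits(cm, "color_map")) stop("expected a color_map")
  v <- as.numeric(v)
  out <- character(length(v))
  out[is.na(v)] <- cm$missing_color
  ok <- which(!is.na(v))
  if (length(ok)) {
    bp <- cm$breakpoints
    rgbs <- hex_to_rgb(cm$colors)
    x <- v[ok]
    i <- findInterval(x, bp)                 # 0..length(bp)
    lo <- pmin(pmax(i, 1L), length(bp) - 1L)
    hi <- lo + 1L
    frac <- (x - bp[lo]) / (bp[hi] - bp[lo])
    frac <- pmin(pmax(frac, 0), 1)           # clamp outside the span
    ch <- rgbs[lo, , drop = FALSE] * (1 - frac) + rgbs[hi, , drop = FALSE] * frac
    out[ok] <- rgb_to_hex(round(ch))
  }
  out
}

#' Default body color map for a matrix
#'
#' Three breakpoints at the working matrix's 5th percentile, median and 95th
#' percentile with a blue-white-red ramp. Degenerate matrices (quantiles not
#' strictly increasing) fall back to an evenly spaced span around the data.
#'
#' @param m a [labeled_matrix()].
#' @return a [color_map()].
#' @export
default_color_map <- function(m) {
  stopifnot_lm(m)
  v <- m$values[!is.na(m$values)]
  if (length(v) == 0) return(color_map(c(0, 1), c("#0000FF", "#FF0000")))
  q <- unname(stats::quantile(v, c(0.05, 0.5, 0.95), type = 7))
  if (any(diff(q) <= 0)) {
    mid <- q[2]
    q <- c(mid - 1, mid, mid + 1)
  }
  color_map(q, c("#0000FF", "#FFFFFF", "#FF0000"))
}

#' Complete heat-map option set
#'
#' The single serializable bundle of every formatting and ordering choice:
#' body color map, per-axis ordering specs, label link-out types (free-text
#' tags such as `"gene symbol"`, recorded for viewers, never resolved here),
#' gap positions, top items to flag on the summary view, covariate bar order,
#' and dendrogram display modes. This object is what the archive writer
#' serializes into the properties document.
#'
#' @param name,description map name and optional description.
#' @param colormap a [color_map()] (or `NULL` to derive a default at build
#'   time).
#' @param row_order,col_order [order_spec()]s.
#' @param row_label_type,col_label_type free-text label type tags.
#' @param row_gaps,col_gaps integer positions (in display order) after which a
#'   gap is inserted; valid positions are `1..n-1`.
#' @param top_items labels to flag in the summary view; unknown labels are
#'   warned about and dropped by [validate_spec()].
#' @param covariate_order list with `row` and `col` character vectors naming
#'   covariates in display order (empty = order of addition).
#' @param dendrogram_display list with `row` and `col` entries, each
#'   `"none"`, `"compact"` or `"full"`.
#' @return a `heat_map_spec`.
#' @export
heat_map_spec <- function(name = "heat map", description = "",
                          colormap = NULL,
                          row_order = order_spec("original"),
                          col_order = order_spec("original"),
                          row_label_type = "text", col_label_type = "text",
                          row_gaps = integer(0), col_gaps = integer(0),
                          top_items = character(0),
                          covariate_order = list(row = character(0),
                                                 col = character(0)),
                          dendrogram_display = list(row = "full", col = "full")) {
  if (!is.null(colormap) && !inherits(colormap, "color_map"))
    stop("colormap must be a color_map or NULL")
  for (o in list(row_order, col_order))
    if (!inherits(o, "order_spec")) stop("row_order/col_order must be order_spec")
  for (dd in dendrogram_display)
    if (!dd %in% c("none", "compact", "full"))
      stop("dendrogram_display entries must be none|compact|full")
  structure(list(name = name, description = description, colormap = colormap,
                 row_order = row_order, col_order = col_order,
                 row_label_type = row_label_type, col_label_type = col_label_type,
                 row_gaps = as.integer(row_gaps), col_gaps = as.integer(col_gaps),
                 top_items = as.character(top_items),
                 covariate_order = covariate_order,
                 dendrogram_display = dendrogram_display),
            class = "heat_map_spec")
}

#' @export
print.heat_map_spec <- function(x, ...) {
  cat(sprintf("<heat_map_spec> '%s': rows %s, cols %s, %d gap(s), %d top item(s)\n",
              x$name, x$row_order$mode, x$col_order$mode,
              length(x$row_gaps) + length(x$col_gaps), length(x$top_items)))
  invisible(x)
}

# fixed gap width, in display cells
GAP_WIDTH <- 2L

#' Lay out an ordered axis with gaps
#'
#' Partitions the display order into contiguous blocks separated by
#' fixed-width (2 cells) blank strips. Data values and ordering are never
#' altered — only the display layout. `slots[i]` gives the display slot of the
#' i-th ordered item; `block_sizes` the partition.
#'
#' @param n number of items on the axis (in display order).
#' @param gaps positions after which a gap is inserted, each in `1..n-1`.
#' @return list with `slots` (length `n`), `block_sizes`, `total_slots`,
#'   `gap_slots` (display slots occupied by gaps).
#' @export
insert_gaps <- function(n, gaps = integer(0)) {
  n <- as.integer(n)
  gaps <- sort(unique(as.integer(gaps)))
  if (length(gaps) && (any(gaps < 1) || any(gaps > n - 1)))
    stop("gap positions must lie in 1..", n - 1L)
  slots <- seq_len(n)
  for (g in gaps) slots[(g + 1L):n] <- slots[(g + 1L):n] + GAP_WIDTH
  bounds <- c(0L, gaps, n)
  block_sizes <- diff(bounds)
  total <- n + GAP_WIDTH * length(gaps)
  gap_slots <- setdiff(seq_len(total), slots)
  list(slots = slots, block_sizes = block_sizes,
       total_slots = total, gap_slots = gap_slots)
}

#' Validate a spec against a session and covariates
#'
#' Cross-checks: gap positions within the working matrix's display range, top
#' items among the row or column labels (unknown items warned and dropped),
#' covariate_order naming known covariates, colormap well-formed. Soft
#' problems come back as warnings in the result; hard inconsistencies raise.
#'
#' @param spec a [heat_map_spec()].
#' @param session a [matrix_session()].
#' @param covariates list of [covariate()].
#' @return list with `spec` (cleaned) and `warnings` (character).
#' @export
validate_spec <- function(spec, session, covariates = list()) {
  if (!inherits(spec, "heat_map_spec")) stop("expected a heat_map_spec")
  if (!inherits(session, "matrix_session")) stop("expected a matrix_session")
  m <- session$working
  warnings <- character(0)
  if (length(spec$row_gaps) && (any(spec$row_gaps < 1) || any(spec$row_gaps > n_rows(m) - 1)))
    stop("row gap position out of range 1..", n_rows(m) - 1L)
  if (length(spec$col_gaps) && (any(spec$col_gaps < 1) || any(spec$col_gaps > n_cols(m) - 1)))
    stop("column gap position out of range 1..", n_cols(m) - 1L)
  if (!is.null(spec$colormap) && any(diff(spec$colormap$breakpoints) <= 0))
    stop("colormap breakpoints must be strictly increasing")
  known <- c(m$row_labels, m$col_labels)
  unknown <- setdiff(spec$top_items, known)
  if (length(unknown)) {
    warnings <- c(warnings, paste0("top item(s) not among matrix labels, dropped: ",
                                   paste(unknown, collapse = ", ")))
    spec$top_items <- setdiff(spec$top_items, unknown)
  }
  cov_names <- vapply(covariates, function(cv) cv$name, "")
  for (ax in c("row", "col")) {
    want <- spec$covariate_order[[ax]]
    have <- cov_names[vapply(covariates, function(cv) cv$axis, "") == ax]
    missing_cov <- setdiff(want, have)
    if (length(missing_cov)) {
      warnings <- c(warnings, paste0("covariate_order names unknown ", ax,
                                     " covariate(s): ",
                                     paste(missing_cov, collapse = ", ")))
      spec$covariate_order[[ax]] <- intersect(want, have)
    }
  }
  list(spec = spec, warnings = warnings)
}
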