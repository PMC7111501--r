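#' Render layout for PDF output
#'
#' Page geometry and the detail-page zoom window. The zoom window is given in
#' display coordinates (after ordering); it defaults to the top-left
#' 50 x 50 display cells.
#'
#' @param width,height page size in inches.
#' @param zoom_rows,zoom_cols integer ranges of display rows/columns for the
#'   detail page (`NULL` = top-left 50 of each).
#' @param label_chars label character budget; longer labels are truncated
#'   with an ellipsis.
#' @return a `render_layout`.
#' @export
render_layout <- function(width = 8.5, height = 11,
                          zoom_rows = NULL, zoom_cols = NULL,
                          label_chars = 18L) {
  structure(list(width = width, height = height,
                 zoom_rows = zoom_rows, zoom_cols = zoom_cols,
                 label_chars = as.integer(label_chars)),
            class = "render_layout")
}

#' Color raster of the heat-map body
#'
#' The renderer's intermediate product: a character matrix of hex colors, one
#' entry per display slot, in display order with gap strips included. Every
#' data cell's color is exactly `map_color(colormap, value)`; gap slots are
#' white. `row_index`/`col_index` map display slots back to working-matrix
#' indices (0 marks a gap slot).
#'
#' @param build a [chm_build()].
#' @return list with `colors` (character matrix), `row_index`, `col_index`.
#' @export
build_raster <- function(build) {
  if (!inherits(build, "chm_build")) stop("expected a chm_build")
  m <- build$session$working
  ro <- build$row_order$order; co <- build$col_order$order
  rlay <- insert_gaps(length(ro), build$spec$row_gaps)
  clay <- insert_gaps(length(co), build$spec$col_gaps)
  colors <- matrix("#FFFFFF", rlay$total_slots, clay$total_slots)
  body <- map_color(build$spec$colormap, m$values[ro, co, drop = FALSE])
  body <- matrix(body, length(ro), length(co))
  colors[rlay$slots, clay$slots] <- body
  row_index <- integer(rlay$total_slots); row_index[rlay$slots] <- ro
  col_index <- integer(clay$total_slots); col_index[clay$slots] <- co
  list(colors = colors, row_index = row_index, col_index = col_index)
}

trunc_label <- function(x, budget) {
  long <- nchar(x) > budget
  x[long] <- paste0(substr(x[long], 1, budget - 2L), "..")
  x
}

# line segments for drawing a dendrogram above/beside ordered leaves;
# returns x0,y0,x1,y1 in leaf-slot / height units
dendro_segments <- function(d, slots, compact = FALSE) {
  n <- length(d$labels)
  if (n < 2) return(NULL)
  pos <- numeric(n)                      # leaf slot centers, by leaf index
  pos[d$leaf_order] <- slots - 0.5
  h <- d$heights
  if (compact) h <- sqrt(h)
  node_x <- numeric(nrow(d$merges)); node_h <- numeric(nrow(d$merges))
  segs <- vector("list", nrow(d$merges))
  for (i in seq_len(nrow(d$merges))) {
    get_xh <- function(ref)
      if (ref < 0) c(pos[-ref], 0) else c(node_x[ref], node_h[ref])
    a <- get_xh(d$merges[i, 1]); b <- get_xh(d$merges[i, 2])
    segs[[i]] <- rbind(
      c(a[1], a[2], a[1], h[i]),     # riser from child a
      c(b[1], b[2], b[1], h[i]),     # riser from child b
      c(a[1], h[i], b[1], h[i]))     # crossbar
    node_x[i] <- (a[1] + b[1]) / 2
    node_h[i] <- h[i]
  }
  out <- do.call(rbind, segs)
  colnames(out) <- c("x0", "y0", "x1", "y1")
  out
}

draw_dendro_panel <- function(d, slots, total_slots, side, compact) {
  segs <- dendro_segments(d, slots, compact)
  if (is.null(segs)) return(invisible())
  hmax <- max(segs[, c(2, 4)])
  if (hmax <= 0) hmax <- 1
  if (side == "top") {
    grid::grid.segments(segs[, 1] / total_slots, segs[, 2] / hmax,
                        segs[, 3] / total_slots, segs[, 4] / hmax,
                        gp = grid::gpar(lwd = 0.5))
  } else {  # left of the body: height grows leftwards, slots run downwards
    grid::grid.segments(1 - segs[, 2] / hmax, 1 - segs[, 1] / total_slots,
                        1 - segs[, 4] / hmax, 1 - segs[, 3] / total_slots,
                        gp = grid::gpar(lwd = 0.5))
  }
}

draw_covariate_strip <- function(cv, m, ord, slots, total_slots, axis) {
  labs <- axis_labels(m, axis)[ord]
  v <- cv$values[labs]
  cols <- if (cv$kind == "continuous") {
    map_color(cv$colors, v)
  } else {
    miss <- attr(cv$colors, "missing_color") %||% "#FFFFFF"
    out <- unname(cv$colors[as.character(v)])
    out[is.na(out)] <- miss
    out
  }
  strip <- rep("#FFFFFF", total_slots)
  strip[slots] <- cols
  if (axis == "col") {
    grid::grid.raster(matrix(strip, nrow = 1), interpolate = FALSE,
                      width = 1, height = 1)
  } else {
    grid::grid.raster(matrix(strip, ncol = 1), interpolate = FALSE,
                      width = 1, height = 1)
  }
  grid::grid.text(cv$name, x = grid::unit(1, "npc") + grid::unit(2, "pt"),
                  just = "left", gp = grid::gpar(cex = 0.45))
}

#' Render a build to a multi-page PDF
#'
#' Page 1 is the summary view: the whole matrix (with gaps), dendrograms on
#' clustered axes (per the spec's display mode), covariate bars, and top-item
#' callouts. Page 2 is the detail view: the zoom window with per-cell colors
#' and row/column labels. The final page holds the legends (body color scale
#' with breakpoints, one legend per covariate) and build metadata. Cell
#' colors come from [build_raster()], so they equal `map_color` of the
#' ordered working matrix by construction.
#'
#' @param build a [chm_build()].
#' @param layout a [render_layout()].
#' @param path output PDF path.
#' @return `path`, invisibly.
#' @export
render_pdf <- function(build, path, layout = render_layout()) {
  if (!inherits(build, "chm_build")) stop("expected a chm_build")
  ras <- build_raster(build)
  m <- build$session$working
  grDevices::pdf(path, width = layout$width, height = layout$height,
                 onefile = TRUE, useDingbats = FALSE)
  on.exit(grDevices::dev.off())

  render_summary_page(build, ras, layout)
  render_detail_page(build, ras, layout)
  render_legend_page(build, layout)
  invisible(path)
}

render_summary_page <- function(build, ras, layout) {
  m <- build$session$working
  spec <- build$spec
  rlay <- insert_gaps(n_rows(m), spec$row_gaps)
  clay <- insert_gaps(n_cols(m), spec$col_gaps)
  row_d <- build$row_order$dendrogram
  col_d <- build$col_order$dendrogram
  show_rd <- !is.null(row_d) && spec$dendrogram_display$row != "none"
  show_cd <- !is.null(col_d) && spec$dendrogram_display$col != "none"
  col_covs <- Filter(function(cv) cv$axis == "col", build$covariates)
  row_covs <- Filter(function(cv) cv$axis == "row", build$covariates)

  grid::grid.newpage()
  grid::grid.text(spec$name, y = 0.975, gp = grid::gpar(fontface = "bold"))

  dendro_depth <- 0.12
  cov_depth <- 0.022
  left <- 0.08 + (if (show_rd) dendro_depth else 0) +
    cov_depth * length(row_covs)
  top <- 0.06 + (if (show_cd) dendro_depth else 0) +
    cov_depth * length(col_covs)
  body_w <- 0.97 - left
  body_h <- 0.95 - top - 0.03

  body_vp <- grid::viewport(x = left, y = 0.03, just = c("left", "bottom"),
                            width = body_w, height = body_h)
  grid::pushViewport(body_vp)
  grid::grid.raster(ras$colors, interpolate = FALSE, width = 1, height = 1)
  grid::grid.rect(gp = grid::gpar(fill = NA, col = "grey40", lwd = 0.5))
  # top-item callouts on the right margin
  if (length(spec$top_items)) {
    ro <- build$row_order$order
    for (item in spec$top_items) {
      ri <- match(item, m$row_labels[ro])
      if (!is.na(ri)) {
        y <- 1 - (rlay$slots[ri] - 0.5) / rlay$total_slots
        grid::grid.segments(1, y, 1.01, y, gp = grid::gpar(col = "black"))
        grid::grid.text(item, x = 1.015, y = y, just = "left",
                        gp = grid::gpar(cex = 0.5))
      }
      ci <- match(item, m$col_labels[build$col_order$order])
      if (!is.na(ci)) {
        x <- (clay$slots[ci] - 0.5) / clay$total_slots
        grid::grid.segments(x, 0, x, -0.01, gp = grid::gpar(col = "black"))
        grid::grid.text(item, x = x, y = -0.015, just = "top", rot = 90,
                        gp = grid::gpar(cex = 0.5))
      }
    }
  }
  grid::popViewport()

  if (show_cd) {
    grid::pushViewport(grid::viewport(
      x = left, y = 0.95 - dendro_depth + 0.005, just = c("left", "bottom"),
      width = body_w, height = dendro_depth - 0.01))
    draw_dendro_panel(col_d, clay$slots, clay$total_slots, "top",
                      compact = spec$dendrogram_display$col == "compact")
    grid::popViewport()
  }
  if (show_rd) {
    grid::pushViewport(grid::viewport(
      x = 0.075, y = 0.03, just = c("left", "bottom"),
      width = dendro_depth - 0.01, height = body_h))
    draw_dendro_panel(row_d, rlay$slots, rlay$total_slots, "left",
                      compact = spec$dendrogram_display$row == "compact")
    grid::popViewport()
  }
  for (i in seq_along(col_covs)) {
    grid::pushViewport(grid::viewport(
      x = left, y = 0.95 - (if (show_cd) dendro_depth else 0) - cov_depth * i + 0.002,
      just = c("left", "bottom"), width = body_w, height = cov_depth - 0.004))
    draw_covariate_strip(col_covs[[i]], build$session$working,
                         build$col_order$order, clay$slots, clay$total_slots, "col")
    grid::popViewport()
  }
  for (i in seq_along(row_covs)) {
    grid::pushViewport(grid::viewport(
      x = left - cov_depth * i + 0.002, y = 0.03,
      just = c("left", "bottom"), width = cov_depth - 0.004, height = body_h))
    draw_covariate_strip(row_covs[[i]], build$session$working,
                         build$row_order$order, rlay$slots, rlay$total_slots, "row")
    grid::popViewport()
  }
}

render_detail_page <- function(build, ras, layout) {
  m <- build$session$working
  zr <- layout$zoom_rows %||% seq_len(min(50L, nrow(ras$colors)))
  zc <- layout$zoom_cols %||% seq_len(min(50L, ncol(ras$colors)))
  if (any(zr < 1) || any(zr > nrow(ras$colors)) ||
      any(zc < 1) || any(zc > ncol(ras$colors)))
    stop("zoom window outside the display extent")
  grid::grid.newpage()
  grid::grid.text(paste0(build$spec$name, " - detail view"), y = 0.975,
                  gp = grid::gpar(fontface = "bold"))
  grid::pushViewport(grid::viewport(x = 0.08, y = 0.05, just = c("left", "bottom"),
                                    width = 0.74, height = 0.84))
  grid::grid.raster(ras$colors[zr, zc, drop = FALSE], interpolate = FALSE,
                    width = 1, height = 1)
  grid::grid.rect(gp = grid::gpar(fill = NA, col = "grey40", lwd = 0.5))
  rl <- ifelse(ras$row_index[zr] > 0, m$row_labels[ras$row_index[zr]], "")
  cl <- ifelse(ras$col_index[zc] > 0, m$col_labels[ras$col_index[zc]], "")
  rl <- trunc_label(rl, layout$label_chars)
  cl <- trunc_label(cl, layout$label_chars)
  cex <- min(0.6, 28 / max(length(zr), length(zc)))
  grid::grid.text(rl, x = 1.005, y = 1 - (seq_along(zr) - 0.5) / length(zr),
                  just = "left", gp = grid::gpar(cex = cex))
  grid::grid.text(cl, x = (seq_along(zc) - 0.5) / length(zc), y = -0.005,
                  just = "right", rot = 90, gp = grid::gpar(cex = cex))
  grid::popViewport()
}

render_legend_page <- function(build, layout) {
  spec <- build$spec
  grid::grid.newpage()
  grid::grid.text("Legends and metadata", y = 0.975,
                  gp = grid::gpar(fontface = "bold"))
  y <- 0.92
  # body color scale
  cm <- spec$colormap
  grid::grid.text("Body colors", x = 0.05, y = y, just = "left",
                  gp = grid::gpar(fontface = "bold", cex = 0.8))
  y <- y - 0.03
  ramp_v <- seq(cm$breakpoints[1], cm$breakpoints[length(cm$breakpoints)],
                length.out = 128)
  grid::pushViewport(grid::viewport(x = 0.05, y = y - 0.015,
                                    just = c("left", "bottom"),
                                    width = 0.4, height = 0.025))
  grid::grid.raster(matrix(map_color(cm, ramp_v), nrow = 1),
                    interpolate = FALSE, width = 1, height = 1)
  grid::grid.rect(gp = grid::gpar(fill = NA, lwd = 0.5))
  rng <- range(cm$breakpoints)
  bx <- (cm$breakpoints - rng[1]) / diff(rng)
  grid::grid.text(format_roundtrip(signif(cm$breakpoints, 4)), x = bx, y = -0.6,
                  gp = grid::gpar(cex = 0.55))
  grid::popViewport()
  grid::grid.text(paste("missing:", cm$missing_color), x = 0.47, y = y,
                  just = "left", gp = grid::gpar(cex = 0.6))
  y <- y - 0.06
  # covariate legends
  for (cv in build$covariates) {
    grid::grid.text(sprintf("%s (%s %s covariate)", cv$name, cv$kind, cv$axis),
                    x = 0.05, y = y, just = "left",
                    gp = grid::gpar(fontface = "bold", cex = 0.7))
    y <- y - 0.025
    if (cv$kind == "discrete") {
      cats <- names(cv$colors)
      for (i in seq_along(cats)) {
        grid::grid.rect(x = 0.06, y = y, width = 0.015, height = 0.012,
                        just = "left",
                        gp = grid::gpar(fill = cv$colors[[i]], col = "grey30"))
        grid::grid.text(cats[i], x = 0.085, y = y, just = "left",
                        gp = grid::gpar(cex = 0.6))
        y <- y - 0.02
      }
      miss <- attr(cv$colors, "missing_color") %||% "#FFFFFF"
      grid::grid.rect(x = 0.06, y = y, width = 0.015, height = 0.012,
                      just = "left", gp = grid::gpar(fill = miss, col = "grey30"))
      grid::grid.text("missing", x = 0.085, y = y, just = "left",
                      gp = grid::gpar(cex = 0.6, fontface = "italic"))
      y <- y - 0.03
    } else {
      cmv <- cv$colors
      vr <- seq(cmv$breakpoints[1], cmv$breakpoints[length(cmv$breakpoints)],
                length.out = 64)
      grid::pushViewport(grid::viewport(x = 0.06, y = y - 0.008,
                                        just = c("left", "bottom"),
                                        width = 0.25, height = 0.015))
      grid::grid.raster(matrix(map_color(cmv, vr), nrow = 1),
                        interpolate = FALSE, width = 1, height = 1)
      grid::grid.rect(gp = grid::gpar(fill = NA, lwd = 0.5))
      grid::popViewport()
      grid::grid.text(sprintf("%g .. %g", cmv$breakpoints[1],
                              cmv$breakpoints[length(cmv$breakpoints)]),
                      x = 0.33, y = y, just = "left", gp = grid::gpar(cex = 0.6))
      y <- y - 0.035
    }
  }
  # metadata block
  m <- build$session$working
  ord_txt <- function(o) {
    switch(o$mode,
           cluster = sprintf("clustered (%s linkage, %s distance)",
                             o$linkage, o$distance),
           random = sprintf("randomized (seed %d)", o$seed),
           "original order")
  }
  meta <- c(
    sprintf("Name: %s", spec$name),
    if (nzchar(spec$description)) sprintf("Description: %s", spec$description),
    sprintf("Matrix: %d rows x %d columns", n_rows(m), n_cols(m)),
    sprintf("Row order: %s", ord_txt(spec$row_order)),
    sprintf("Column order: %s", ord_txt(spec$col_order)),
    sprintf("Row labels: %s; column labels: %s",
            spec$row_label_type, spec$col_label_type),
    sprintf("Transform history: %d step(s)", length(build$session$history)),
    if (length(spec$top_items))
      sprintf("Top items: %s", paste(spec$top_items, collapse = ", "))
  )
  grid::grid.text(paste(meta, collapse = "\n"), x = 0.05, y = y - 0.02,
                  just = c("left", "top"), gp = grid::gpar(cex = 0.65))
}
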