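NGCHM_SCHEMA_VERSION <- "1.0"
PROPERTIES_FILE <- "heatmapProperties.json"
ARCHIVE_EPOCH <- "2020-01-01 00:00:00 UTC"

#' Complete heat-map build state
#'
#' Everything a finished map consists of: the transform session (original +
#' working matrix + history), the display orderings and any dendrograms, the
#' covariate bars, the complete option set, and the creation log. This is the
#' object [write_ngchm()] serializes and [replay()] reconstructs.
#'
#' @param session a [matrix_session()].
#' @param row_order,col_order results of [order_axis()] (lists with `order`
#'   and `dendrogram`).
#' @param covariates list of [covariate()]s (colors already assigned).
#' @param spec a [heat_map_spec()]; a `NULL` colormap is replaced by
#'   [default_color_map()] of the working matrix.
#' @param log a [creation_log()] (optional; empty by default).
#' @return a `chm_build`.
#' @export
chm_build <- function(session, row_order, col_order, covariates = list(),
                      spec = heat_map_spec(), log = creation_log()) {
  if (!inherits(session, "matrix_session")) stop("expected a matrix_session")
  m <- session$working
  for (nm in c("order")) {
    if (is.null(row_order[[nm]]) || is.null(col_order[[nm]]))
      stop("row_order/col_order must be order_axis() results")
  }
  if (!setequal(row_order$order, seq_len(n_rows(m))))
    stop("row order is not a permutation of the working rows")
  if (!setequal(col_order$order, seq_len(n_cols(m))))
    stop("column order is not a permutation of the working columns")
  chk <- validate_spec(spec, session, covariates)
  spec <- chk$spec
  if (is.null(spec$colormap)) spec$colormap <- default_color_map(m)
  for (cv in covariates) {
    extra <- setdiff(names(cv$values), axis_labels(m, cv$axis))
    if (length(extra))
      stop("covariate '", cv$name, "' has labels not on the matrix ", cv$axis,
           " axis: ", paste(utils::head(extra, 3), collapse = ", "))
  }
  covariates <- lapply(covariates, function(cv) {
    if (is.null(cv$colors)) default_colors(cv) else cv
  })
  structure(list(session = session, row_order = row_order,
                 col_order = col_order, covariates = covariates,
                 spec = spec, log = log, warnings = chk$warnings),
            class = "chm_build")
}

#' @export
print.chm_build <- function(x, ...) {
  m <- x$session$working
  cat(sprintf("<chm_build> '%s': %d x %d, rows %s / cols %s, %d covariate(s), %d log event(s)\n",
              x$spec$name, n_rows(m), n_cols(m),
              x$spec$row_order$mode, x$spec$col_order$mode,
              length(x$covariates), length(x$log$events)))
  invisible(x)
}

## ---- serialization helpers -------------------------------------------------

order_spec_to_list <- function(o) {
  Filter(Negate(is.null),
         list(mode = o$mode, linkage = o$linkage, distance = o$distance,
              seed = o$seed))
}

order_spec_from_list <- function(l) {
  order_spec(mode = l$mode, linkage = l$linkage, distance = l$distance,
             seed = l$seed)
}

dendro_to_list <- function(d) {
  if (is.null(d)) return(NULL)
  list(merges = unclass(d$merges), heights = d$heights,
       leaf_order = d$leaf_order, labels = d$labels, axis = d$axis,
       linkage = d$linkage, distance = d$distance)
}

dendro_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  merges <- l$merges
  if (is.list(merges)) merges <- do.call(rbind, merges)
  merges <- matrix(as.integer(merges), ncol = 2)
  structure(list(merges = merges, heights = as.numeric(l$heights),
                 leaf_order = as.integer(l$leaf_order),
                 labels = as.character(l$labels), axis = l$axis,
                 linkage = l$linkage, distance = l$distance),
            class = "chm_dendrogram")
}

colormap_to_list <- function(cm) {
  list(breakpoints = cm$breakpoints, colors = cm$colors,
       missing_color = cm$missing_color)
}

colormap_from_list <- function(l) {
  color_map(as.numeric(l$breakpoints), as.character(l$colors),
            as.character(l$missing_color))
}

cov_meta_to_list <- function(cv, file) {
  colors <- cv$colors
  if (cv$kind == "discrete") {
    list(name = cv$name, axis = cv$axis, kind = cv$kind, file = file,
         position = cv$position,
         category_colors = as.list(colors),
         missing_color = attr(colors, "missing_color"))
  } else {
    list(name = cv$name, axis = cv$axis, kind = cv$kind, file = file,
         position = cv$position, colormap = colormap_to_list(colors))
  }
}

spec_to_list <- function(spec) {
  list(name = spec$name, description = spec$description,
       colormap = colormap_to_list(spec$colormap),
       row_order = order_spec_to_list(spec$row_order),
       col_order = order_spec_to_list(spec$col_order),
       row_label_type = spec$row_label_type,
       col_label_type = spec$col_label_type,
       row_gaps = spec$row_gaps, col_gaps = spec$col_gaps,
       top_items = spec$top_items,
       covariate_order = spec$covariate_order,
       dendrogram_display = spec$dendrogram_display)
}

spec_from_list <- function(l) {
  heat_map_spec(
    name = l$name, description = l$description %||% "",
    colormap = colormap_from_list(l$colormap),
    row_order = order_spec_from_list(l$row_order),
    col_order = order_spec_from_list(l$col_order),
    row_label_type = l$row_label_type, col_label_type = l$col_label_type,
    row_gaps = as.integer(unlist(l$row_gaps)),
    col_gaps = as.integer(unlist(l$col_gaps)),
    top_items = as.character(unlist(l$top_items)),
    covariate_order = list(row = as.character(unlist(l$covariate_order$row)),
                           col = as.character(unlist(l$covariate_order$col))),
    dendrogram_display = list(row = l$dendrogram_display$row,
                              col = l$dendrogram_display$col))
}

# working matrix permuted into display order
display_matrix <- function(build) {
  m <- build$session$working
  ro <- build$row_order$order; co <- build$col_order$order
  labeled_matrix(m$values[ro, co, drop = FALSE],
                 m$row_labels[ro], m$col_labels[co], m$n_invalid)
}

write_covariate_file <- function(cv, path) {
  v <- cv$values
  txt <- if (cv$kind == "continuous") format_roundtrip(as.numeric(v))
         else ifelse(is.na(v), "NA", as.character(v))
  writeLines(paste(names(v), txt, sep = "\t"), path, useBytes = TRUE)
}

read_covariate_payload <- function(path, meta) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[[`, "", 1L)
  vals <- vapply(parts, `[[`, "", 2L)
  if (meta$kind == "continuous") {
    v <- suppressWarnings(as.numeric(vals))
    colors <- colormap_from_list(meta$colormap)
  } else {
    v <- ifelse(vals == "NA", NA_character_, vals)
    colors <- stats::setNames(unlist(meta$category_colors),
                              names(meta$category_colors))
    if (length(colors) == 0) colors <- character(0)
    attr(colors, "missing_color") <- meta$missing_color
  }
  covariate(meta$name, meta$axis, meta$kind, stats::setNames(v, keys),
            colors = colors, position = meta$position)
}

## ---- archive writer / reader ----------------------------------------------

#' Write a build as an NG-CHM style archive
#'
#' The archive is a single zip around a directory whose anchor is the
#' `heatmapProperties.json` options document (versioned schema; contains the
#' full [heat_map_spec()], axis orders and permutations, dendrogram merge
#' tables, covariate metadata and the file manifest). Alongside it: the
#' working matrix in display order (tab-delimited), per-axis Newick
#' dendrograms when clustered, one payload file per covariate bar, and the
#' canonical (timestamp-free) creation log. Entries are written in sorted
#' name order with fixed timestamps: equal builds produce byte-identical
#' archives.
#'
#' @param build a [chm_build()].
#' @param path output `.ngchm` file.
#' @return `path`, invisibly.
#' @export
write_ngchm <- function(build, path) {
  if (!inherits(build, "chm_build")) stop("expected a chm_build")
  stage <- tempfile("ngchm_stage_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE))

  entries <- character(0)
  add <- function(rel) entries <<- c(entries, rel)

  dm <- display_matrix(build)
  write_matrix(dm, file.path(stage, "matrix.tsv")); add("matrix.tsv")

  writeLines(serialize_log(build$log, timestamps = FALSE),
             file.path(stage, "creation.log"), useBytes = TRUE)
  add("creation.log")

  for (ax in c("row", "col")) {
    d <- build[[paste0(ax, "_order")]]$dendrogram
    if (!is.null(d)) {
      f <- paste0(ax, "_dendrogram.newick")
      writeLines(dendrogram_to_newick(d), file.path(stage, f), useBytes = TRUE)
      add(f)
    }
  }

  cov_meta <- list()
  if (length(build$covariates)) {
    dir.create(file.path(stage, "covariates"))
    for (i in seq_along(build$covariates)) {
      cv <- build$covariates[[i]]
      f <- sprintf("covariates/%02d_%s_%s.tsv", i, cv$axis,
                   gsub("[^A-Za-z0-9_.-]", "_", cv$name))
      write_covariate_file(cv, file.path(stage, f)); add(f)
      cov_meta[[i]] <- cov_meta_to_list(cv, f)
    }
  }

  props <- list(
    schema_version = NGCHM_SCHEMA_VERSION,
    spec = spec_to_list(build$spec),
    row_permutation = build$row_order$order,
    col_permutation = build$col_order$order,
    row_dendrogram = dendro_to_list(build$row_order$dendrogram),
    col_dendrogram = dendro_to_list(build$col_order$dendrogram),
    covariates = cov_meta,
    n_invalid = build$session$working$n_invalid,
    history = as.list(serialize_steps(build$session$history)),
    manifest = as.list(sort(c(entries, PROPERTIES_FILE)))
  )
  # 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(props, file.path(stage, PROPERTIES_FILE),
                       auto_unbox = TRUE, pretty = TRUE, digits = I(17),
                       null = "null")
  add(PROPERTIES_FILE)

  entries <- sort(entries)
  # freeze timestamps so equal builds give byte-identical archives
  epoch <- as.POSIXct(ARCHIVE_EPOCH, tz = "UTC")
  for (f in c(entries, list.dirs(stage, full.names = FALSE, recursive = TRUE)))
    Sys.setFileTime(file.path(stage, f), epoch)
  if (file.exists(path)) unlink(path)
  zip::zip(zipfile = file.path(normalizePath(dirname(path)), basename(path)),
           files = entries, root = stage, mode = "mirror",
           include_directories = FALSE)
  invisible(path)
}

#' Read an NG-CHM style archive back into a build state
#'
#' Reconstructs the display matrix, orders, dendrograms, covariates, option
#' set and creation log written by [write_ngchm()]. The original (pre-
#' transform) matrix is not part of the archive, so the returned session
#' carries the working matrix and its history only; [replay()] with the
#' original input restores the full state. Unknown extra archive entries are
#' preserved opaquely in `$extras`.
#'
#' @param path an `.ngchm` file.
#' @return a `chm_build` (with `$extras`: named list of raw vectors for
#'   unrecognized entries).
#' @export
read_ngchm <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  exdir <- tempfile("ngchm_read_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  listing <- tryCatch(zip::zip_list(path), error = function(e)
    stop("'", path, "' is not a valid archive: ", conditionMessage(e)))
  tryCatch(zip::unzip(path, exdir = exdir), error = function(e)
    stop("'", path, "' is not a valid archive: ", conditionMessage(e)))
  pf <- file.path(exdir, PROPERTIES_FILE)
  if (!file.exists(pf))
    stop("archive has no ", PROPERTIES_FILE, " — not an NG-CHM archive")
  props <- jsonlite::read_json(pf, simplifyVector = FALSE)
  for (key in c("schema_version", "spec", "row_permutation", "col_permutation"))
    if (is.null(props[[key]]))
      stop("properties document missing required key '", key, "'")

  spec <- spec_from_list(props$spec)
  dm <- parse_matrix(file.path(exdir, "matrix.tsv"))
  dm$n_invalid <- as.integer(props$n_invalid %||% 0L)
  ro <- as.integer(unlist(props$row_permutation))
  co <- as.integer(unlist(props$col_permutation))
  # invert the display permutation to recover the working matrix
  inv_r <- order(ro); inv_c <- order(co)
  working <- labeled_matrix(dm$values[inv_r, inv_c, drop = FALSE],
                            dm$row_labels[inv_r], dm$col_labels[inv_c],
                            dm$n_invalid)
  session <- matrix_session(working)
  session$history <- parse_steps(unlist(props$history))
  session$original <- NULL      # not stored in the archive

  covs <- lapply(props$covariates, function(meta)
    read_covariate_payload(file.path(exdir, meta$file), meta))

  log_path <- file.path(exdir, "creation.log")
  log <- if (file.exists(log_path)) parse_log(readLines(log_path, warn = FALSE))
         else creation_log()

  build <- structure(
    list(session = session,
         row_order = list(order = ro,
                          dendrogram = dendro_from_list(props$row_dendrogram)),
         col_order = list(order = co,
                          dendrogram = dendro_from_list(props$col_dendrogram)),
         covariates = covs, spec = spec, log = log, warnings = character(0)),
    class = "chm_build")
  known <- unlist(props$manifest)
  extras_names <- setdiff(listing$filename, c(known, paste0(unique(dirname(known)), "/")))
  extras_names <- extras_names[!endsWith(extras_names, "/")]
  build$extras <- stats::setNames(
    lapply(extras_names, function(f)
      readBin(file.path(exdir, f), "raw", file.size(file.path(exdir, f)))),
    extras_names)
  build
}

#' Compare two build states field by field
#'
#' Equality on the comparable surface of a build: working matrix cells and
#' labels, permutations, dendrogram merge structure and heights, covariate
#' values/kinds/colors, and every spec field. The preserved original matrix
#' is deliberately excluded (archives do not carry it).
#'
#' @param a,b `chm_build` objects.
#' @return logical scalar.
#' @export
build_equal <- function(a, b) {
  if (!lm_equal(a$session$working, b$session$working)) return(FALSE)
  if (!identical(a$row_order$order, b$row_order$order)) return(FALSE)
  if (!identical(a$col_order$order, b$col_order$order)) return(FALSE)
  deq <- function(x, y) {
    if (is.null(x) != is.null(y)) return(FALSE)
    if (is.null(x)) return(TRUE)
    identical(x$merges, y$merges) && isTRUE(all.equal(x$heights, y$heights)) &&
      identical(x$leaf_order, y$leaf_order) && identical(x$labels, y$labels)
  }
  if (!deq(a$row_order$dendrogram, b$row_order$dendrogram)) return(FALSE)
  if (!deq(a$col_order$dendrogram, b$col_order$dendrogram)) return(FALSE)
  if (length(a$covariates) != length(b$covariates)) return(FALSE)
  for (i in seq_along(a$covariates)) {
    ca <- a$covariates[[i]]; cb <- b$covariates[[i]]
    if (!identical(ca$name, cb$name) || !identical(ca$axis, cb$axis) ||
        !identical(ca$kind, cb$kind)) return(FALSE)
    va <- ca$values; vb <- cb$values
    if (!identical(names(va), names(vb))) return(FALSE)
    if (ca$kind == "continuous") {
      if (!identical(is.na(va), is.na(vb))) return(FALSE)
      if (!isTRUE(all.equal(unname(va[!is.na(va)]), unname(vb[!is.na(vb)]))))
        return(FALSE)
    } else if (!identical(unname(va), unname(vb))) return(FALSE)
  }
  sa <- spec_to_list(a$spec); sb <- spec_to_list(b$spec)
  isTRUE(all.equal(sa, sb, tolerance = 0))
}
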