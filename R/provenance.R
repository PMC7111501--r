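LOG_STEPS <- c("select_matrix", "transform", "cluster", "covariate",
               "format", "output")

#' Creation log
#'
#' The ordered record of every option chosen while building a map: one event
#' per record, with a builder step name, an action, a parameter map and an
#' optional timestamp. The log is the single source of truth for
#' reproducibility — together with the original input files it suffices to
#' recreate the map exactly (see [replay()]). Timestamps are informational
#' only and excluded from the canonical serialization embedded in archives.
#'
#' @param events list of event records (normally built up via [record()]).
#' @return a `creation_log`.
#' @export
creation_log <- function(events = list()) {
  structure(list(events = events), class = "creation_log")
}

#' Append an event to a creation log
#'
#' @param log a [creation_log()].
#' @param step builder step name: one of
#'   `select_matrix`, `transform`, `cluster`, `covariate`, `format`, `output`.
#' @param action action name within the step.
#' @param params named list of scalar parameters.
#' @param timestamp POSIXct or `NULL`.
#' @return the extended log.
#' @export
record <- function(log, step, action, params = list(), timestamp = Sys.time()) {
  if (!inherits(log, "creation_log")) stop("expected a creation_log")
  if (!step %in% LOG_STEPS)
    stop("unknown builder step '", step, "'")
  if (length(params) && (is.null(names(params)) || any(!nzchar(names(params)))))
    stop("all event parameters must be named")
  ev <- list(step = step, action = action, params = params,
             timestamp = timestamp)
  log$events <- c(log$events, list(ev))
  log
}

#' @export
print.creation_log <- function(x, ...) {
  cat("<creation_log>", length(x$events), "event(s)\n")
  for (ln in serialize_log(x, timestamps = FALSE)[-1]) cat(" ", ln, "\n")
  invisible(x)
}

LOG_HEADER <- "# chmforge creation log v1"

fmt_param <- function(v) {
  if (is.numeric(v)) format_roundtrip(v) else as.character(v)
}

#' Serialize / parse a creation log
#'
#' Human-readable text, one event per line:
#' `step<TAB>action<TAB>key=value;key=value[<TAB>timestamp]`, under a header
#' line. With `timestamps = FALSE` the canonical form is produced (this is
#' what archives embed, so replayed archives are byte-identical).
#'
#' @param log a [creation_log()].
#' @param timestamps include timestamps?
#' @return `serialize_log`: character vector of lines (header first).
#' @export
serialize_log <- function(log, timestamps = TRUE) {
  lines <- vapply(log$events, function(ev) {
    kv <- vapply(names(ev$params), function(k) {
      v <- fmt_param(ev$params[[k]])
      if (grepl("[\t;]", v)) stop("log parameter values may not contain tab or ';'")
      paste0(k, "=", v)
    }, "")
    base <- paste(ev$step, ev$action, paste(kv, collapse = ";"), sep = "\t")
    if (timestamps && !is.null(ev$timestamp))
      base <- paste(base, format(ev$timestamp, "%Y-%m-%dT%H:%M:%OS3%z"), sep = "\t")
    base
  }, "")
  c(LOG_HEADER, lines)
}

#' @rdname serialize_log
#' @param lines character vector as written by `serialize_log` (header
#'   optional).
#' @return `parse_log`: a [creation_log()].
#' @export
parse_log <- function(lines) {
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#")]
  events <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed log line: ", ln)
    params <- list()
    if (length(parts) >= 3 && nzchar(parts[3])) {
      for (kv in strsplit(parts[3], ";", fixed = TRUE)[[1]]) {
        eq <- regexpr("=", kv, fixed = TRUE)
        k <- substr(kv, 1, eq - 1)
        v <- substr(kv, eq + 1, nchar(kv))
        num <- suppressWarnings(as.numeric(v))
        params[[k]] <- if (!is.na(num) && grepl("^[-+0-9.eE]+$", v)) num else v
      }
    }
    ts <- if (length(parts) >= 4)
      as.POSIXct(parts[4], format = "%Y-%m-%dT%H:%M:%OS%z") else NULL
    list(step = parts[1], action = parts[2], params = params, timestamp = ts)
  })
  creation_log(events)
}

## ---- high-level build driver ----------------------------------------------

#' Build a complete heat map, recording every option in a creation log
#'
#' Runs the builder's step order end to end: parse the matrix (optionally
#' with embedded covariates), apply transform steps, enforce the clustering
#' size gate, order both axes, attach covariates (files, derived top-branch
#' covariates), apply the format spec, and assemble a [chm_build()] whose log
#' captures every choice. The build can be serialized with [write_ngchm()],
#' rendered with [render_pdf()], and recreated exactly with [replay()].
#'
#' @param matrix_path input matrix file (`.txt`, `.csv` or `.xlsx`).
#' @param region optional [region_spec()].
#' @param transforms list of [transform_step()]s to apply in order.
#' @param row_order,col_order [order_spec()]s.
#' @param covariate_files named list: name -> list(path=, axis=, kind=).
#' @param top_branch_covariates list of lists `list(axis =, k =)` deriving a
#'   discrete covariate from the clustering dendrogram of that axis.
#' @param spec a [heat_map_spec()]; its `row_order`/`col_order` are set from
#'   the arguments; `NULL` colormap gets the data-driven default.
#' @param size_limit clustering size gate on rows + columns (default 5000).
#' @param source_name the input file name to record in the log (defaults to
#'   the matrix file's base name; lets a session that works on a stored copy
#'   log the name of the file the user originally supplied).
#' @return a `chm_build`.
#' @export
build_heatmap <- function(matrix_path, region = NULL, transforms = list(),
                          row_order = order_spec("original"),
                          col_order = order_spec("original"),
                          covariate_files = list(),
                          top_branch_covariates = list(),
                          spec = heat_map_spec(), size_limit = 5000,
                          source_name = basename(matrix_path)) {
  log <- creation_log()
  p_region <- if (is.null(region)) region_spec() else region
  log <- record(log, "select_matrix", "open",
                list(file = source_name,
                     label_row = p_region$label_row,
                     label_col = p_region$label_col,
                     data_row = p_region$data_origin[1],
                     data_col = p_region$data_origin[2],
                     name = spec$name))
  m <- parse_matrix(matrix_path, region)
  session <- matrix_session(m)
  for (st in transforms) {
    session <- apply_step(session, st)
    log <- record(log, "transform", st$action, st$params)
  }
  check_size(session$working, limit = size_limit)

  spec$row_order <- row_order
  spec$col_order <- col_order
  ro <- order_axis(session$working, "row", row_order)
  log <- record(log, "cluster", "order_rows", order_spec_to_list(row_order))
  co <- order_axis(session$working, "col", col_order)
  log <- record(log, "cluster", "order_cols", order_spec_to_list(col_order))

  covs <- list()
  for (nm in names(covariate_files)) {
    cf <- covariate_files[[nm]]
    labs <- axis_labels(session$working, cf$axis)
    cv <- parse_covariate(cf$path, cf$axis, cf$kind, labs, name = nm)
    cv$position <- length(covs) + 1L
    covs <- c(covs, list(cv))
    log <- record(log, "covariate", "add_file",
                  list(name = nm, file = basename(cf$path), axis = cf$axis,
                       kind = cf$kind))
  }
  for (tb in top_branch_covariates) {
    d <- if (tb$axis == "row") ro$dendrogram else co$dendrogram
    if (is.null(d))
      stop("top-branch covariate requires a clustered ", tb$axis, " axis")
    cv <- cut_top_branches(d, tb$k)
    cv$position <- length(covs) + 1L
    covs <- c(covs, list(cv))
    log <- record(log, "covariate", "top_branches",
                  list(axis = tb$axis, k = tb$k))
  }

  if (is.null(spec$colormap)) spec$colormap <- default_color_map(session$working)
  log <- record(log, "format", "set_spec",
                list(spec = as.character(jsonlite::toJSON(
                  spec_to_list(spec), auto_unbox = TRUE, digits = I(17)))))
  build <- chm_build(session, ro, co, covs, spec, log)
  build$log <- record(build$log, "output", "build",
                      list(size_limit = size_limit))
  build
}

#' Recreate a build exactly from the original input and a creation log
#'
#' Replays every recorded option against the original matrix file (and the
#' covariate files the log references, supplied through `covariate_paths`).
#' The result is equal to the build that produced the log, option for option
#' and cell for cell; writing it with [write_ngchm()] yields a byte-identical
#' archive.
#'
#' @param matrix_path the original input matrix file.
#' @param log a [creation_log()] (or a path to a serialized log file).
#' @param covariate_paths named character vector mapping the file names
#'   recorded in the log to their current paths; defaults to the recorded
#'   names resolved against the matrix file's directory.
#' @return a `chm_build`.
#' @export
replay <- function(matrix_path, log, covariate_paths = NULL) {
  if (is.character(log) && length(log) == 1 && file.exists(log))
    log <- parse_log(readLines(log, warn = FALSE))
  if (!inherits(log, "creation_log")) stop("expected a creation_log")
  region <- NULL
  source_name <- basename(matrix_path)
  transforms <- list()
  row_order <- order_spec("original"); col_order <- order_spec("original")
  covariate_files <- list()
  top_branches <- list()
  spec <- heat_map_spec()
  size_limit <- 5000
  for (ev in log$events) {
    p <- ev$params
    if (ev$step == "select_matrix") {
      source_name <- p$file %||% source_name
      region <- region_spec(label_row = p$label_row %||% 0,
                            label_col = p$label_col %||% 0,
                            data_origin = c(p$data_row %||% 1, p$data_col %||% 1))
    } else if (ev$step == "transform") {
      transforms <- c(transforms,
                      list(do.call(transform_step,
                                   c(list(action = ev$action), p))))
    } else if (ev$step == "cluster") {
      os <- order_spec(mode = p$mode, linkage = p$linkage,
                       distance = p$distance, seed = p$seed)
      if (ev$action == "order_rows") row_order <- os else col_order <- os
    } else if (ev$step == "covariate" && ev$action == "add_file") {
      path <- if (!is.null(covariate_paths) && p$file %in% names(covariate_paths))
        covariate_paths[[p$file]]
      else file.path(dirname(matrix_path), p$file)
      if (!file.exists(path))
        stop("replay needs covariate file '", p$file, "' (looked at ", path, ")")
      covariate_files[[p$name]] <- list(path = path, axis = p$axis, kind = p$kind)
    } else if (ev$step == "covariate" && ev$action == "top_branches") {
      top_branches <- c(top_branches, list(list(axis = p$axis, k = p$k)))
    } else if (ev$step == "format" && ev$action == "set_spec") {
      spec <- spec_from_list(jsonlite::fromJSON(p$spec, simplifyVector = FALSE))
    } else if (ev$step == "output") {
      size_limit <- p$size_limit %||% size_limit
    }
  }
  build_heatmap(matrix_path, region = region, transforms = transforms,
                row_order = row_order, col_order = col_order,
                covariate_files = covariate_files,
                top_branch_covariates = top_branches,
                spec = spec, size_limit = size_limit,
                source_name = source_name)
}
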