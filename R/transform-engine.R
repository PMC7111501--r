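#' @name transforms
#' @title Matrix transforms and filters
#'
#' @description
#' The transform vocabulary applied to a working matrix during heat-map
#' preparation. Each function is pure: it takes a [labeled_matrix()] and
#' returns a new one. For a replayable history, apply them through a
#' [matrix_session()] with [apply_step()].
#'
#' Conventions shared by all transforms:
#' * missing cells are `NA` and stay `NA` unless a function says otherwise;
#' * "below" a threshold means strictly less than;
#' * standard deviation uses denominator `n - 1` over non-missing cells, and a
#'   vector with fewer than 2 non-missing cells has SD 0 (so it sorts last);
#' * a vector's missing percentage is computed against the full axis length.
NULL

#' Set values below a cutoff to missing
#'
#' Cells strictly less than `cutoff` become missing; cells equal to or above
#' it are untouched. Used to suppress noise-level values before a log
#' transform (e.g. cutoff `1e-5`).
#'
#' @param m a [labeled_matrix()].
#' @param cutoff finite number.
#' @return transformed matrix.
#' @export
threshold_na <- function(m, cutoff) {
  stopifnot_lm(m)
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  m$values[!is.na(m$values) & m$values < cutoff] <- NA_real_
  m
}

#' Logarithm transform
#'
#' Each positive cell becomes its log in the given base; cells `<= 0` become
#' missing rather than erroring, on the expectation that a later
#' missing-data filter removes offending rows.
#'
#' @param m a [labeled_matrix()].
#' @param base log base, `> 0` and `!= 1` (default 10).
#' @return transformed matrix.
#' @export
log_transform <- function(m, base = 10) {
  stopifnot_lm(m)
  if (!is.finite(base) || base <= 0 || base == 1)
    stop("log base must be positive and != 1")
  v <- m$values
  nonpos <- !is.na(v) & v <= 0
  v[nonpos] <- NA_real_
  ok <- !is.na(v)
  v[ok] <- log(v[ok], base = base)
  m$values <- v
  m
}

#' Mean-center rows or columns
#'
#' Subtracts each vector's mean over its non-missing cells; an all-missing
#' vector is left unchanged. After the transform every vector's non-missing
#' mean is 0 (within floating-point error).
#'
#' @param m a [labeled_matrix()].
#' @param axis `"row"` or `"col"`.
#' @return transformed matrix.
#' @export
mean_center <- function(m, axis) {
  stopifnot_lm(m); check_axis(axis)
  if (axis == "row") {
    mu <- rowMeans(m$values, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    m$values <- m$values - mu
  } else {
    mu <- colMeans(m$values, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    m$values <- sweep(m$values, 2L, mu)
  }
  m
}

#' Transpose the matrix
#'
#' Rows and columns (values and labels) exchange; applying it twice is the
#' identity.
#' @param m a [labeled_matrix()].
#' @return transposed matrix.
#' @export
transpose_matrix <- function(m) {
  stopifnot_lm(m)
  labeled_matrix(t(m$values), m$col_labels, m$row_labels, m$n_invalid)
}

#' Pairwise correlation matrix along an axis
#'
#' Pearson correlation between every pair of vectors on `axis`, using
#' pairwise-complete observations. The result is square and symmetric with the
#' axis labels on both sides and unit diagonal. A pair in which either vector
#' has zero variance over the shared positions yields a missing cell (with a
#' warning).
#'
#' @param m a [labeled_matrix()].
#' @param axis `"row"` or `"col"`.
#' @param method only `"pearson"`.
#' @return a square [labeled_matrix()] of correlations.
#' @export
correlation_matrix <- function(m, axis, method = "pearson") {
  stopifnot_lm(m); check_axis(axis)
  if (!identical(method, "pearson")) stop("only pearson correlation is supported")
  x <- axis_vectors(m, axis)  # vectors as rows
  if (nrow(x) < 2) stop("correlation needs at least 2 vectors on the axis")
  obs <- !is.na(x)
  shared <- tcrossprod(obs * 1)
  if (any(shared < 2))
    stop("some vector pairs share fewer than 2 non-missing positions")
  r <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs",
                                   method = "pearson"))
  diag(r) <- 1
  if (any(is.na(r)))
    warning("zero-variance vector pair(s): correlation undefined, set to missing")
  labs <- axis_labels(m, axis)
  labeled_matrix(r, labs, labs, m$n_invalid)
}

#' Replace missing cells with a constant
#'
#' @param m a [labeled_matrix()].
#' @param strategy only `"constant"`.
#' @param value finite replacement value.
#' @return matrix with no missing cells.
#' @export
replace_missing <- function(m, strategy = "constant", value) {
  stopifnot_lm(m)
  if (!identical(strategy, "constant")) stop("unsupported strategy '", strategy, "'")
  if (!is.finite(value)) stop("replacement value must be finite")
  m$values[is.na(m$values)] <- value
  m
}

#' Remove vectors with too many missing values
#'
#' A vector is removed when its missing fraction, as a percentage of the full
#' axis length, is *strictly greater* than `max_pct`; a vector at exactly
#' `max_pct` is retained. Survivor order is preserved.
#'
#' @param m a [labeled_matrix()].
#' @param axis `"row"` or `"col"`.
#' @param max_pct percentage in `[0, 100]`.
#' @return filtered matrix.
#' @export
filter_missing <- function(m, axis, max_pct) {
  stopifnot_lm(m); check_axis(axis)
  if (!is.finite(max_pct) || max_pct < 0 || max_pct > 100)
    stop("max_pct must be in [0, 100]")
  na <- is.na(m$values)
  pct <- if (axis == "row") rowMeans(na) * 100 else colMeans(na) * 100
  keep <- pct <= max_pct
  if (!any(keep)) stop("filter would remove every ", axis, " (empty matrix)")
  subset_axis(m, axis, which(keep))
}

#' Keep the most variable vectors
#'
#' Retains the `keep_n` vectors with the highest sample standard deviation
#' (denominator `n - 1`, over non-missing cells), in their original relative
#' order. Ties at the boundary are broken in favour of the earlier vector. If
#' the axis already has `<= keep_n` vectors the matrix is returned unchanged.
#'
#' @param m a [labeled_matrix()].
#' @param axis `"row"` or `"col"`.
#' @param keep_n number of vectors to keep, `>= 1`.
#' @return filtered matrix.
#' @export
filter_top_sd <- function(m, axis, keep_n) {
  stopifnot_lm(m); check_axis(axis)
  keep_n <- as.integer(keep_n)
  if (is.na(keep_n) || keep_n < 1) stop("keep_n must be >= 1")
  sds <- axis_sd(m, axis)
  n <- length(sds)
  if (n <= keep_n) return(m)
  ord <- order(-sds, seq_len(n))     # stable: earlier vector wins ties
  keep <- sort(ord[seq_len(keep_n)])
  subset_axis(m, axis, keep)
}

axis_sd <- function(m, axis) {
  x <- axis_vectors(m, axis)
  nobs <- rowSums(!is.na(x))
  s <- apply(x, 1L, stats::sd, na.rm = TRUE)
  s[nobs < 2 | is.na(s)] <- 0       # degenerate vectors sort last
  s
}

subset_axis <- function(m, axis, idx) {
  if (axis == "row") {
    labeled_matrix(m$values[idx, , drop = FALSE], m$row_labels[idx],
                   m$col_labels, m$n_invalid)
  } else {
    labeled_matrix(m$values[, idx, drop = FALSE], m$row_labels,
                   m$col_labels[idx], m$n_invalid)
  }
}

## ---- transform steps & sessions -------------------------------------------

STEP_ACTIONS <- c("threshold_na", "log", "mean_center_row", "mean_center_col",
                  "transpose", "correlation", "replace_missing",
                  "filter_missing_row", "filter_missing_col",
                  "filter_sd_row", "filter_sd_col", "dedupe")

#' A single, serializable transform step
#'
#' Steps name an action from the fixed transform vocabulary plus its
#' parameters. A step serializes to one text line (see
#' [serialize_steps()]) and replaying the parsed line is identical to
#' replaying the original.
#'
#' @param action one of `r paste0('\x60', STEP_ACTIONS, '\x60', collapse = ", ")`.
#' @param ... named scalar parameters (numbers or strings).
#' @return a `transform_step`.
#' @export
transform_step <- function(action, ...) {
  if (!action %in% STEP_ACTIONS)
    stop("unknown transform action '", action, "'")
  params <- list(...)
  if (length(params) && (is.null(names(params)) || any(names(params) == "")))
    stop("all step parameters must be named")
  for (p in params) {
    if (length(p) != 1 || !(is.numeric(p) || is.character(p)))
      stop("step parameters must be scalar numbers or strings")
  }
  structure(list(action = action, params = params), class = "transform_step")
}

#' @export
print.transform_step <- function(x, ...) {
  cat(serialize_steps(list(x)), "\n")
  invisible(x)
}

run_step <- function(m, step) {
  p <- step$params
  switch(step$action,
    threshold_na       = threshold_na(m, as.numeric(p$cutoff)),
    log                = log_transform(m, as.numeric(p$base %||% 10)),
    mean_center_row    = mean_center(m, "row"),
    mean_center_col    = mean_center(m, "col"),
    transpose          = transpose_matrix(m),
    correlation        = correlation_matrix(m, p$axis %||% "row"),
    replace_missing    = replace_missing(m, value = as.numeric(p$value)),
    filter_missing_row = filter_missing(m, "row", as.numeric(p$max_pct)),
    filter_missing_col = filter_missing(m, "col", as.numeric(p$max_pct)),
    filter_sd_row      = filter_top_sd(m, "row", as.numeric(p$keep_n)),
    filter_sd_col      = filter_top_sd(m, "col", as.numeric(p$keep_n)),
    dedupe             = dedupe_labels(m, p$axis %||% "col"),
    stop("unknown transform action '", step$action, "'")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transform session: original + working matrix + replayable history
#'
#' A session preserves the uploaded matrix untouched and applies every
#' transform to a working copy while recording it in an ordered history.
#' Undoing is implemented exactly as restoring the original and re-applying a
#' prefix of the history, so `working == replay(original, history)` always
#' holds.
#'
#' @param original a [labeled_matrix()].
#' @return a `matrix_session`.
#' @seealso [apply_step()], [undo_to()], [replay_steps()]
#' @export
matrix_session <- function(original) {
  stopifnot_lm(original)
  structure(list(original = original, working = original, history = list()),
            class = "matrix_session")
}

#' @export
print.matrix_session <- function(x, ...) {
  cat(sprintf("<matrix_session> original %dx%d, working %dx%d, %d step(s)\n",
              n_rows(x$original), n_cols(x$original),
              n_rows(x$working), n_cols(x$working), length(x$history)))
  for (s in x$history) cat("  - ", serialize_steps(list(s)), "\n", sep = "")
  invisible(x)
}

#' Apply a transform step to a session
#'
#' The step runs against the working matrix; on success the result replaces
#' the working matrix and the step is appended to the history. On error the
#' session is unchanged.
#'
#' @param s a [matrix_session()].
#' @param step a [transform_step()].
#' @return the updated session.
#' @export
apply_step <- function(s, step) {
  if (!inherits(s, "matrix_session")) stop("expected a matrix_session")
  if (!inherits(step, "transform_step")) stop("expected a transform_step")
  s$working <- run_step(s$working, step)
  s$history <- c(s$history, list(step))
  s
}

#' Revert a session to an earlier history state
#'
#' Restores the original matrix and re-applies the first `k` history steps;
#' the history is truncated to those `k` steps. `undo_to(s, 0)` recovers the
#' original upload.
#'
#' @param s a [matrix_session()].
#' @param k number of steps to keep, `0 <= k <= length(history)`.
#' @return the reverted session.
#' @export
undo_to <- function(s, k) {
  if (!inherits(s, "matrix_session")) stop("expected a matrix_session")
  k <- as.integer(k)
  if (is.na(k) || k < 0 || k > length(s$history))
    stop("undo index out of range [0, ", length(s$history), "]")
  kept <- s$history[seq_len(k)]
  s$working <- replay_steps(s$original, kept)
  s$history <- kept
  s
}

#' Replay a list of transform steps on a matrix
#'
#' @param m a [labeled_matrix()].
#' @param steps list of [transform_step()].
#' @return the transformed matrix.
#' @export
replay_steps <- function(m, steps) {
  for (st in steps) m <- run_step(m, st)
  m
}

#' Serialize / parse transform steps
#'
#' One step per line: `action<TAB>key=value;key=value`. Numeric parameters are
#' written with round-trip precision so a parsed line replays identically to
#' the original step. This line format is also the transform payload of the
#' creation log.
#'
#' @param steps list of [transform_step()].
#' @return `serialize_steps`: character vector of lines.
#' @export
serialize_steps <- function(steps) {
  vapply(steps, function(st) {
    kv <- vapply(names(st$params), function(k) {
      v <- st$params[[k]]
      v <- if (is.numeric(v)) format_roundtrip(v) else as.character(v)
      if (grepl("[\t;=]", v)) stop("step parameter values may not contain tab, ';' or '='")
      paste0(k, "=", v)
    }, "")
    paste0(st$action, "\t", paste(kv, collapse = ";"))
  }, "")
}

#' @rdname serialize_steps
#' @param lines character vector as produced by `serialize_steps`.
#' @return `parse_steps`: list of [transform_step()].
#' @export
parse_steps <- function(lines) {
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    action <- parts[1]
    params <- list()
    if (length(parts) > 1 && nzchar(parts[2])) {
      for (kv in strsplit(parts[2], ";", fixed = TRUE)[[1]]) {
        eq <- regexpr("=", kv, fixed = TRUE)
        k <- substr(kv, 1, eq - 1)
        v <- substr(kv, eq + 1, nchar(kv))
        num <- suppressWarnings(as.numeric(v))
        params[[k]] <- if (!is.na(num) && grepl("^[-+0-9.eE]+$", v)) num else v
      }
    }
    do.call(transform_step, c(list(action = action), params))
  })
}

#' Summary statistics for a matrix
#'
#' Row/column counts, a histogram of all non-missing cells over equal-width
#' bins spanning the observed range (all-equal data collapses to a single
#' bin), the invalid-cell count recorded at parse time, and advisory flags:
#' matrix over the clustering size limit, duplicate labels, invalid cells
#' present. Histogram counts always sum to the number of non-missing cells.
#'
#' @param m a [labeled_matrix()].
#' @param n_bins number of histogram bins (default 10).
#' @param size_limit advisory clustering size limit on rows + columns.
#' @return a `chm_summary` list with fields `n_rows`, `n_cols`, `n_missing`,
#'   `n_invalid`, `breaks`, `counts`, `flags`.
#' @export
summarize_matrix <- function(m, n_bins = 10, size_limit = 5000) {
  stopifnot_lm(m)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1) stop("n_bins must be >= 1")
  v <- m$values[!is.na(m$values)]
  if (length(v) == 0) {
    breaks <- numeric(0); counts <- integer(0)
  } else {
    rng <- range(v)
    if (rng[1] == rng[2]) {
      breaks <- rng; counts <- length(v)
    } else {
      breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
      h <- graphics::hist(v, breaks = breaks, plot = FALSE,
                          include.lowest = TRUE, right = TRUE)
      counts <- h$counts
    }
  }
  flags <- character(0)
  if (n_rows(m) + n_cols(m) > size_limit)
    flags <- c(flags, sprintf("matrix exceeds clustering size limit (%d rows + %d cols > %d)",
                              n_rows(m), n_cols(m), size_limit))
  if (anyDuplicated(m$row_labels)) flags <- c(flags, "duplicate row labels present")
  if (anyDuplicated(m$col_labels)) flags <- c(flags, "duplicate column labels present")
  if (m$n_invalid > 0)
    flags <- c(flags, sprintf("%d invalid cell(s) converted to missing", m$n_invalid))
  structure(list(n_rows = n_rows(m), n_cols = n_cols(m),
                 n_missing = sum(is.na(m$values)), n_invalid = m$n_invalid,
                 breaks = breaks, counts = as.integer(counts), flags = flags),
            class = "chm_summary")
}

#' @export
print.chm_summary <- function(x, ...) {
  cat(sprintf("%d x %d matrix, %d missing, %d invalid at parse\n",
              x$n_rows, x$n_cols, x$n_missing, x$n_invalid))
  if (length(x$counts))
    cat("histogram counts:", paste(x$counts, collapse = " "), "\n")
  for (f in x$flags) cat("flag:", f, "\n")
  invisible(x)
}
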