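#' Simulate an expression-like matrix with planted structure
#'
#' Generates the kind of matrix the builder is pointed at: positive,
#' log-normally distributed values (bulk expression-like dynamic range) with
#' planted row and column clusters, an injectable fraction of missing cells,
#' and optionally duplicated column labels (as happens when sample sheets are
#' pasted together). Row clusters are blocks of genes whose (log-scale) mean
#' is shifted in a subset of column clusters, so well-separated cluster
#' structure is recoverable by hierarchical clustering.
#'
#' Defaults mirror the worked use case: 2000 rows (genes) by 100 columns
#' (samples), values `exp(N(mu, sd))` with baseline `mu = 1.5`, `sd = 1`,
#' cluster shifts of `delta = 2` on the log scale, 5% missing cells, and a
#' pinch of sub-threshold noise values so a noise floor cutoff has something
#' to do.
#'
#' @param n_rows,n_cols matrix dimensions.
#' @param n_row_clusters,n_col_clusters planted cluster counts (>= 1).
#' @param delta log-scale mean shift of expressed blocks (cluster separation).
#' @param sdlog log-scale standard deviation of cell noise.
#' @param missing_frac fraction of cells set missing.
#' @param tiny_frac fraction of cells replaced by values below `1e-5`
#'   (noise floor fodder for a threshold transform).
#' @param dup_cols how many column labels to duplicate (0 = none).
#' @param seed RNG seed; the generator never disturbs the caller's RNG state.
#' @return list with `matrix` (a [labeled_matrix()]), `row_cluster` and
#'   `col_cluster` (integer planted assignments, in matrix order).
#' @export
simulate_expression_matrix <- function(n_rows = 2000, n_cols = 100,
                                       n_row_clusters = 4, n_col_clusters = 4,
                                       delta = 2, sdlog = 1,
                                       missing_frac = 0.05, tiny_frac = 0.01,
                                       dup_cols = 0, seed = 1) {
  with_local_seed(seed, {
    row_cluster <- sort(rep_len(seq_len(n_row_clusters), n_rows))
    col_cluster <- sort(rep_len(seq_len(n_col_clusters), n_cols))
    mu <- matrix(1.5, n_rows, n_cols)
    # block shifts: row cluster r is up-shifted in the matching column cluster
    for (r in seq_len(n_row_clusters)) {
      cc <- ((r - 1L) %% n_col_clusters) + 1L
      mu[row_cluster == r, col_cluster == cc] <-
        mu[row_cluster == r, col_cluster == cc] + delta
    }
    vals <- exp(mu + matrix(stats::rnorm(n_rows * n_cols, sd = sdlog),
                            n_rows, n_cols))
    ncell <- n_rows * n_cols
    if (tiny_frac > 0) {
      idx <- sample.int(ncell, round(tiny_frac * ncell))
      vals[idx] <- stats::runif(length(idx), 1e-9, 9e-6)
    }
    if (missing_frac > 0) {
      idx <- sample.int(ncell, round(missing_frac * ncell))
      vals[idx] <- NA_real_
    }
    row_labels <- sprintf("gene_%04d", seq_len(n_rows))
    col_labels <- sprintf("sample_%03d", seq_len(n_cols))
    if (dup_cols > 0) {
      dup_cols <- min(dup_cols, n_cols - 1L)
      src <- sample.int(n_cols - 1L, dup_cols)
      col_labels[src + 1L] <- col_labels[src]
    }
    list(matrix = labeled_matrix(vals, row_labels, col_labels),
         row_cluster = row_cluster, col_cluster = col_cluster)
  })
}

#' Simulate covariate values matched to a label vector
#'
#' Builds one discrete covariate from a planted cluster assignment (category
#' names like `"Group A"`) and one continuous covariate (age-like values,
#' uniform 40..80), both keyed by the given labels, with an optional missing
#' fraction.
#'
#' @param labels axis labels the covariates should be keyed by.
#' @param cluster integer assignment per label (drives the discrete groups).
#' @param axis `"row"` or `"col"`.
#' @param missing_frac fraction of entries set missing.
#' @param seed RNG seed.
#' @return list of two [covariate()]s (`discrete`, `continuous`).
#' @export
simulate_covariates <- function(labels, cluster, axis = "col",
                                missing_frac = 0.05, seed = 1) {
  with_local_seed(seed, {
    disc <- paste("Group", LETTERS[cluster])
    cont <- round(stats::runif(length(labels), 40, 80))
    if (missing_frac > 0) {
      di <- sample.int(length(labels), round(missing_frac * length(labels)))
      ci <- sample.int(length(labels), round(missing_frac * length(labels)))
      disc[di] <- NA_character_
      cont[ci] <- NA_real_
    }
    list(discrete = covariate("group", axis, "discrete",
                              stats::setNames(disc, labels)),
         continuous = covariate("age", axis, "continuous",
                                stats::setNames(cont, labels), position = 2L))
  })
}

#' Write a synthetic fixture set to disk
#'
#' Materializes a simulated matrix and covariates as the files a user would
#' upload: a tab-delimited matrix (optionally with a fraction of data cells
#' replaced by invalid tokens to exercise invalid-cell counting) and one file
#' per covariate. All text, all seeded.
#'
#' @param dir output directory (created if needed).
#' @param sim result of [simulate_expression_matrix()].
#' @param invalid_frac fraction of data cells replaced by a non-numeric token.
#' @param covariates optional list of [covariate()]s to write alongside.
#' @param seed RNG seed for invalid-cell placement.
#' @return named character vector of file paths (`matrix`, plus one per
#'   covariate name).
#' @export
write_fixture_files <- function(dir, sim, invalid_frac = 0, covariates = list(),
                                seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, "matrix.txt")
  write_matrix(sim$matrix, mpath)
  if (invalid_frac > 0) {
    lines <- readLines(mpath)
    with_local_seed(seed, {
      body <- strsplit(lines[-1], "\t", fixed = TRUE)
      nc <- n_cols(sim$matrix)
      ncell <- length(body) * nc
      idx <- sample.int(ncell, max(1L, round(invalid_frac * ncell)))
      for (ix in idx) {
        r <- ((ix - 1L) %/% nc) + 1L
        cc <- ((ix - 1L) %% nc) + 2L    # field 1 is the row label
        body[[r]][cc] <- "not_a_number"
      }
      lines <- c(lines[1], vapply(body, paste, "", collapse = "\t"))
    })
    writeLines(lines, mpath)
  }
  out <- c(matrix = mpath)
  for (cv in covariates) {
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", cv$name), ".txt"))
    v <- cv$values
    v_chr <- ifelse(is.na(v), "NA",
                    if (cv$kind == "continuous") format_roundtrip(as.numeric(v))
                    else as.character(v))
    writeLines(paste(names(v), v_chr, sep = "\t"), p)
    out[cv$name] <- p
  }
  out
}
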