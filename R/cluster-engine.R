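#' Axis ordering specification
#'
#' How one axis of the heat map is ordered: by agglomerative hierarchical
#' clustering (`mode = "cluster"`, which requires a linkage and a distance
#' metric), left in original order, or randomized with a recorded seed so the
#' shuffle is reproducible.
#'
#' @param mode `"cluster"`, `"original"` or `"random"`.
#' @param linkage `"ward"`, `"complete"`, `"average"` or `"single"`
#'   (cluster mode only). `"ward"` uses ward.D2 semantics: the squared-distance
#'   update on unsquared Euclidean input.
#' @param distance `"euclidean"`, `"manhattan"` or `"correlation"`
#'   (cluster mode only); correlation distance is `1 - r` (Pearson).
#' @param seed integer (random mode only).
#' @return an `order_spec`.
#' @export
order_spec <- function(mode = c("cluster", "original", "random"),
                       linkage = NULL, distance = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "cluster") {
    if (is.null(linkage) || is.null(distance))
      stop("cluster mode requires linkage and distance")
    linkage <- match.arg(linkage, c("ward", "complete", "average", "single"))
    distance <- match.arg(distance, c("euclidean", "manhattan", "correlation"))
    seed <- NULL
  } else if (mode == "random") {
    if (is.null(seed)) stop("random mode requires a seed")
    seed <- as.integer(seed)
    linkage <- distance <- NULL
  } else {
    linkage <- distance <- seed <- NULL
  }
  structure(list(mode = mode, linkage = linkage, distance = distance,
                 seed = seed), class = "order_spec")
}

#' @export
print.order_spec <- function(x, ...) {
  extra <- switch(x$mode,
    cluster = sprintf(" (%s linkage, %s distance)", x$linkage, x$distance),
    random  = sprintf(" (seed %d)", x$seed),
    "")
  cat("<order_spec> ", x$mode, extra, "\n", sep = "")
  invisible(x)
}

#' Enforce the clustering size gate
#'
#' The interactive builder refuses to cluster matrices with more than `limit`
#' total rows plus columns (default 5000, e.g. 1000 samples and 4000 genes
#' passes); larger uploads must first be reduced with filters. Passes silently
#' when within the limit.
#'
#' @param m a [labeled_matrix()].
#' @param limit maximum of `n_rows + n_cols`.
#' @return `TRUE` invisibly, or an error naming both dimensions.
#' @export
check_size <- function(m, limit = 5000) {
  stopifnot_lm(m)
  total <- n_rows(m) + n_cols(m)
  if (total > limit)
    stop(sprintf("matrix too large to cluster: %d rows + %d columns = %d > limit %d; filter it down first",
                 n_rows(m), n_cols(m), total, limit))
  invisible(TRUE)
}

#' Pairwise distance matrix along an axis
#'
#' Distances between all vectors on `axis`. Missing values are handled with
#' pairwise-complete positions: for euclidean and manhattan the partial sum
#' over the `k` shared positions is rescaled by `m/k` (total positions over
#' shared positions) before the final root/sum, matching the conventional
#' `dist()` treatment. Correlation distance is `1 - r` with Pearson `r` over
#' pairwise-complete observations.
#'
#' @param m a [labeled_matrix()].
#' @param axis `"row"` or `"col"`.
#' @param metric `"euclidean"`, `"manhattan"` or `"correlation"`.
#' @return symmetric numeric matrix with zero diagonal, labeled on both axes.
#' @export
distance_matrix <- function(m, axis, metric = c("euclidean", "manhattan", "correlation")) {
  stopifnot_lm(m); check_axis(axis)
  metric <- match.arg(metric)
  x <- axis_vectors(m, axis)
  if (nrow(x) < 2) stop("need at least 2 vectors on the axis")
  obs <- !is.na(x)
  shared <- tcrossprod(obs * 1)
  diag(shared) <- Inf                    # only pairs matter below
  if (any(shared == 0))
    stop("some vector pairs share no non-missing positions; distance undefined")
  if (metric == "correlation") {
    if (any(shared < 2))
      stop("some vector pairs share fewer than 2 non-missing positions")
    r <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
    if (any(is.na(r)))
      stop("zero-variance vector(s): correlation distance undefined")
    d <- 1 - r
    diag(d) <- 0
    d[d < 0] <- 0   # guard tiny negative rounding of 1 - r
  } else {
    d <- as.matrix(stats::dist(x, method = metric))
  }
  labs <- axis_labels(m, axis)
  dimnames(d) <- list(labs, labs)
  d
}

#' Agglomerative hierarchical clustering of one axis
#'
#' Clusters the vectors on `axis` under `spec$linkage` applied to
#' [distance_matrix()] with `spec$distance`. The merge table follows the
#' usual convention (negative entries reference leaves, positive entries
#' earlier merges). The leaf order is made deterministic by always drawing the
#' subtree containing the smallest original index on the left.
#'
#' @param m a [labeled_matrix()].
#' @param axis `"row"` or `"col"`.
#' @param spec an [order_spec()] with `mode = "cluster"`.
#' @return a `chm_dendrogram` with fields `merges` ((n-1) x 2), `heights`,
#'   `leaf_order` (1-based permutation), `labels`, `axis`, `linkage`,
#'   `distance`. A single-vector axis yields a degenerate dendrogram with no
#'   merges.
#' @export
cluster_axis <- function(m, axis, spec) {
  stopifnot_lm(m); check_axis(axis)
  if (!inherits(spec, "order_spec") || spec$mode != "cluster")
    stop("spec must be an order_spec with mode = \"cluster\"")
  labs <- axis_labels(m, axis)
  n <- length(labs)
  if (n < 2) {
    return(new_dendrogram(matrix(integer(0), 0, 2), numeric(0),
                          seq_len(n), labs, axis, spec))
  }
  d <- distance_matrix(m, axis, spec$distance)
  method <- if (spec$linkage == "ward") "ward.D2" else spec$linkage
  hc <- stats::hclust(stats::as.dist(d), method = method)
  new_dendrogram(hc$merge, hc$height, leaf_order_from_merges(hc$merge),
                 labs, axis, spec)
}

new_dendrogram <- function(merges, heights, leaf_order, labels, axis, spec) {
  structure(list(merges = merges, heights = as.numeric(heights),
                 leaf_order = as.integer(leaf_order),
                 labels = labels, axis = axis,
                 linkage = spec$linkage, distance = spec$distance),
            class = "chm_dendrogram")
}

#' @export
print.chm_dendrogram <- function(x, ...) {
  cat(sprintf("<chm_dendrogram> %d leaves on %s axis (%s linkage, %s distance)\n",
              length(x$labels), x$axis, x$linkage, x$distance))
  invisible(x)
}

# Deterministic leaf ordering from a merge table: at every internal node the
# child subtree containing the smallest original leaf index goes left.
# Iterative over merges (children always precede parents) to avoid deep
# recursion on large chained dendrograms.
leaf_order_from_merges <- function(merges) {
  k <- nrow(merges)
  if (k == 0) return(1L)
  orders <- vector("list", k)
  mins <- integer(k)
  node <- function(ref) {
    if (ref < 0) list(ord = -ref, min = -ref)
    else list(ord = orders[[ref]], min = mins[ref])
  }
  for (i in seq_len(k)) {
    a <- node(merges[i, 1]); b <- node(merges[i, 2])
    if (a$min <= b$min) {
      orders[[i]] <- c(a$ord, b$ord)
    } else {
      orders[[i]] <- c(b$ord, a$ord)
    }
    mins[i] <- min(a$min, b$min)
  }
  as.integer(orders[[k]])
}

#' Order an axis by clustering, original order, or seeded shuffle
#'
#' @param m a [labeled_matrix()].
#' @param axis `"row"` or `"col"`.
#' @param spec an [order_spec()].
#' @return a list with `order` (1-based permutation of the axis) and
#'   `dendrogram` (a `chm_dendrogram`, or `NULL` unless `mode = "cluster"`).
#' @export
order_axis <- function(m, axis, spec) {
  stopifnot_lm(m); check_axis(axis)
  if (!inherits(spec, "order_spec")) stop("expected an order_spec")
  n <- if (axis == "row") n_rows(m) else n_cols(m)
  if (spec$mode == "original") {
    list(order = seq_len(n), dendrogram = NULL)
  } else if (spec$mode == "random") {
    list(order = with_local_seed(spec$seed, sample.int(n)), dendrogram = NULL)
  } else {
    d <- cluster_axis(m, axis, spec)
    list(order = d$leaf_order, dendrogram = d)
  }
}

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a cluster covariate from the top branches of a dendrogram
#'
#' Removing the `k - 1` highest merges leaves `k` subtrees; each leaf is
#' assigned to its subtree's category. Categories are labeled
#' `"Cluster 1" .. "Cluster k"` in order of first appearance along the leaf
#' order (left to right on the drawn map). The result is a discrete covariate
#' for the dendrogram's axis.
#'
#' @param d a `chm_dendrogram` from [cluster_axis()].
#' @param k number of top branches, `1 <= k <=` number of leaves.
#' @param name covariate name.
#' @return a discrete [covariate()].
#' @export
cut_top_branches <- function(d, k, name = sprintf("Top %d branches", k)) {
  if (!inherits(d, "chm_dendrogram")) stop("expected a chm_dendrogram")
  n <- length(d$labels)
  k <- as.integer(k)
  if (is.na(k) || k < 1 || k > n) stop("k must be in [1, ", n, "]")
  # union over the first (n - k) merges (the k - 1 highest merges removed)
  grp <- -seq_len(n)                 # each leaf its own group, keyed by node ref
  leaf_grp <- -seq_len(n)
  merge_grp <- integer(max(0L, n - 1L))
  n_use <- n - k
  if (n_use > 0) {
    for (i in seq_len(n_use)) {
      a <- d$merges[i, 1]; b <- d$merges[i, 2]
      ga <- if (a < 0) a else merge_grp[a]
      gb <- if (b < 0) b else merge_grp[b]
      leaf_grp[leaf_grp == gb] <- ga
      merge_grp[merge_grp == gb] <- ga
      merge_grp[i] <- ga
    }
  } else if (n > 1) {
    merge_grp[] <- 0L
  }
  # number clusters by first appearance in leaf order
  ordered_grp <- leaf_grp[d$leaf_order]
  first_seen <- unique(ordered_grp)
  cat_idx <- match(leaf_grp, first_seen)
  vals <- paste("Cluster", cat_idx)
  names(vals) <- d$labels
  covariate(name = name, axis = d$axis, kind = "discrete", values = vals)
}

#' Export a dendrogram as Newick text
#'
#' Leaf names are the axis labels; branch lengths are height differences
#' between a node and its parent (leaves sit at height 0). Children follow the
#' same smallest-index-left convention as the leaf order, and numbers use
#' round-trip formatting, so output is deterministic.
#'
#' @param d a `chm_dendrogram`.
#' @return a single Newick string terminated by `;`.
#' @export
dendrogram_to_newick <- function(d) {
  if (!inherits(d, "chm_dendrogram")) stop("expected a chm_dendrogram")
  n <- length(d$labels)
  esc <- gsub("[ ,:;()\\[\\]']", "_", d$labels)
  if (n == 1) return(paste0(esc, ";"))
  k <- nrow(d$merges)
  strs <- character(k); mins <- integer(k); hts <- d$heights
  node_str <- function(ref) if (ref < 0) esc[-ref] else strs[ref]
  node_min <- function(ref) if (ref < 0) -ref else mins[ref]
  node_h <- function(ref) if (ref < 0) 0 else hts[ref]
  for (i in seq_len(k)) {
    a <- d$merges[i, 1]; b <- d$merges[i, 2]
    if (node_min(b) < node_min(a)) { tmp <- a; a <- b; b <- tmp }
    la <- format_roundtrip(hts[i] - node_h(a))
    lb <- format_roundtrip(hts[i] - node_h(b))
    strs[i] <- paste0("(", node_str(a), ":", la, ",", node_str(b), ":", lb, ")")
    mins[i] <- min(node_min(a), node_min(b))
  }
  paste0(strs[k], ";")
}
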