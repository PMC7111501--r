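test_that("the size gate passes at the limit and rejects above it", {
  ok <- labeled_matrix(matrix(0, 10, 5))
  expect_true(check_size(ok))
  expect_true(check_size(labeled_matrix(matrix(0, 1, 1))))
  big <- labeled_matrix(matrix(0, 4501, 500))
  err <- tryCatch(check_size(big), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "4501")
  expect_match(conditionMessage(err), "500")
  # configurable limit
  expect_error(check_size(ok, limit = 10), "too large")
})

test_that("distances match hand geometry and the per-pair formula oracle", {
  m <- labeled_matrix(rbind(c(0, 0), c(3, 4)))
  expect_equal(distance_matrix(m, "row", "euclidean")[1, 2], 5)
  expect_equal(distance_matrix(m, "row", "manhattan")[1, 2], 7)
  ident <- labeled_matrix(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(distance_matrix(ident, "row", "correlation")[1, 2], 0)

  set.seed(11)
  x <- matrix(rnorm(60), 6, 10)
  x[sample(60, 6)] <- NA
  lm6 <- labeled_matrix(x)
  for (metric in c("euclidean", "manhattan", "correlation")) {
    d <- distance_matrix(lm6, "row", metric)
    o <- oracle_distance_matrix(x, metric)
    expect_lt(max(abs(d - o)), 1e-10)
    expect_equal(diag(d), setNames(rep(0, 6), lm6$row_labels))
    expect_equal(d, t(d))
  }
  # a pair with no shared observed positions is an error
  y <- rbind(c(1, NA, 2, NA), c(NA, 3, NA, 4), c(1, 2, 3, 4))
  expect_error(distance_matrix(labeled_matrix(y), "row", "euclidean"),
               "no non-missing")
})

test_that("single linkage on 1-D points {0,1,10,11} merges the near pairs first", {
  m <- labeled_matrix(matrix(c(0, 1, 10, 11), 4, 1))
  d <- cluster_axis(m, "row", order_spec("cluster", "single", "manhattan"))
  expect_equal(d$heights[1:2], c(1, 1))
  expect_equal(d$heights[3], 9)
  first_two <- vapply(1:2, function(i)
    paste(sort(abs(d$merges[i, ])), collapse = "-"), "")
  expect_setequal(first_two, c("1-2", "3-4"))
})

test_that("merge heights and partitions match a naive O(n^3) oracle", {
  set.seed(21)
  combos <- expand.grid(linkage = c("ward", "complete", "average", "single"),
                        metric = c("euclidean", "manhattan", "correlation"),
                        stringsAsFactors = FALSE)
  for (rep in 1:6) {
    n <- sample(4:14, 1)
    x <- matrix(rnorm(n * 8), n, 8)
    m <- labeled_matrix(x)
    for (i in seq_len(nrow(combos))) {
      lk <- combos$linkage[i]; mt <- combos$metric[i]
      d <- cluster_axis(m, "row", order_spec("cluster", lk, mt))
      o <- oracle_agglomerate(oracle_distance_matrix(x, mt), lk)
      expect_lt(max(abs(d$heights - o$heights)), 1e-9)
      for (k in c(2, min(4, n))) {
        expect_identical(partition_from_merges(d$merges, n, k),
                         partition_from_merges(o$merges, n, k))
      }
    }
  }
})

test_that("leaf order is a valid deterministic permutation with min-index left", {
  sim <- simulate_expression_matrix(n_rows = 40, n_cols = 10, seed = 8)
  d <- cluster_axis(sim$matrix, "row", order_spec("cluster", "ward", "euclidean"))
  expect_setequal(d$leaf_order, seq_len(40))
  expect_equal(d$leaf_order[1] <= 40, TRUE)
  # smallest original index appears in the left subtree at the root
  root <- nrow(d$merges)
  expect_equal(d$leaf_order[1], min(d$leaf_order))
  d2 <- cluster_axis(sim$matrix, "row", order_spec("cluster", "ward", "euclidean"))
  expect_identical(d, d2)
})

test_that("cutting at k then k+1 refines the partition", {
  sim <- simulate_expression_matrix(n_rows = 30, n_cols = 8, seed = 9)
  d <- cluster_axis(sim$matrix, "row", order_spec("cluster", "average", "euclidean"))
  for (k in 2:6) {
    a <- cut_top_branches(d, k)$values
    b <- cut_top_branches(d, k + 1)$values
    # each class at k+1 lies inside one class at k
    for (cl in unique(b)) {
      expect_length(unique(a[b == cl]), 1L)
    }
  }
})

test_that("ward merge heights are non-decreasing (variance criterion)", {
  for (seed in 1:4) {
    sim <- simulate_expression_matrix(n_rows = 25, n_cols = 6, seed = seed)
    d <- cluster_axis(sim$matrix, "row", order_spec("cluster", "ward", "euclidean"))
    expect_true(all(diff(d$heights) >= -1e-12))
  }
})

test_that("axis ordering honours original, seeded-random and cluster modes", {
  m <- labeled_matrix(matrix(rnorm(50), 5, 10))
  expect_equal(order_axis(m, "row", order_spec("original"))$order, 1:5)

  big <- labeled_matrix(matrix(rnorm(1000), 100, 10))
  r1 <- order_axis(big, "row", order_spec("random", seed = 7))$order
  r2 <- order_axis(big, "row", order_spec("random", seed = 7))$order
  r3 <- order_axis(big, "row", order_spec("random", seed = 8))$order
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))
  expect_setequal(r1, 1:100)

  cl <- order_axis(m, "row", order_spec("cluster", "complete", "euclidean"))
  expect_identical(cl$order, cl$dendrogram$leaf_order)
  # RNG state of the caller is not disturbed by seeded ordering
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(order_axis(big, "row", order_spec("random", seed = 7)))
  expect_identical(rnorm(1), before)
})

test_that("order_spec validates its mode-dependent fields", {
  expect_error(order_spec("cluster"), "linkage")
  expect_error(order_spec("random"), "seed")
  expect_silent(order_spec("original"))
})

test_that("top-branch covariates recover planted clusters and edge cases", {
  sim <- simulate_expression_matrix(n_rows = 60, n_cols = 40,
                                    n_row_clusters = 4, n_col_clusters = 4,
                                    missing_frac = 0, tiny_frac = 0, seed = 10)
  pre <- mean_center(log_transform(sim$matrix, 10), "row")
  d <- cluster_axis(pre, "col", order_spec("cluster", "ward", "euclidean"))
  cov4 <- cut_top_branches(d, 4)
  expect_s3_class(cov4, "covariate")
  expect_equal(cov4$axis, "col")
  expect_length(unique(cov4$values), 4L)
  # same partition as planted, up to labeling
  tab <- table(cov4$values, sim$col_cluster)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))

  one <- cut_top_branches(d, 1)
  expect_equal(unique(unname(one$values)), "Cluster 1")
  full <- cut_top_branches(d, 40)
  expect_length(unique(full$values), 40L)
  expect_error(cut_top_branches(d, 0), "k must be")
  expect_error(cut_top_branches(d, 41), "k must be")
  # numbering follows leaf order: leftmost leaf is always Cluster 1
  leftmost <- d$labels[d$leaf_order[1]]
  expect_equal(unname(cov4$values[leftmost]), "Cluster 1")
})

test_that("degenerate single-leaf axes cluster without error", {
  m <- labeled_matrix(matrix(1:3, 1, 3), "only", c("a", "b", "c"))
  d <- cluster_axis(m, "row", order_spec("cluster", "ward", "euclidean"))
  expect_equal(d$leaf_order, 1L)
  expect_equal(nrow(d$merges), 0L)
})

test_that("newick export round-trips through an independent tree parser", {
  skip_if_not_installed("ape")
  sim <- simulate_expression_matrix(n_rows = 12, n_cols = 6, seed = 12)
  d <- cluster_axis(sim$matrix, "row", order_spec("cluster", "average", "euclidean"))
  nwk <- dendrogram_to_newick(d)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, d$labels)
  # root-to-tip depth equals the root merge height for ultrametric linkages
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  expect_lt(max(abs(depths - max(d$heights))), 1e-8)
})
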