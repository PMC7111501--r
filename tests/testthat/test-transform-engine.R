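test_that("threshold keeps the boundary value and blanks strictly-below cells", {
  m <- labeled_matrix(matrix(c(1e-6, 1e-5, 2e-5, 5), 2, 2))
  t <- threshold_na(m, 1e-5)
  expect_true(is.na(t$values[1, 1]))       # 1e-6 < cutoff
  expect_equal(t$values[2, 1], 1e-5)       # boundary survives
  expect_equal(t$values[, 2], c(2e-5, 5))
  # identity when everything is at or above the cutoff
  m2 <- labeled_matrix(matrix(c(1, 2, 3, 4), 2, 2))
  expect_true(lm_equal(threshold_na(m2, 0.5), m2))
})

test_that("log transform maps positives, blanks non-positives, keeps missing", {
  m <- labeled_matrix(matrix(c(1000, 1, 0, -2, NA, 10), 2, 3))
  t <- log_transform(m, 10)
  expect_equal(t$values[1, 1], 3)
  expect_equal(t$values[2, 1], 0)
  expect_true(all(is.na(t$values[, 2])))
  expect_true(is.na(t$values[1, 3]))
  expect_equal(t$values[2, 3], 1)
  expect_error(log_transform(m, 1), "base")
  expect_error(log_transform(m, -2), "base")
})

test_that("mean centering zeroes non-missing means on either axis", {
  m <- labeled_matrix(matrix(c(1, 5, 2, NA, 3, 7), 2, 3))
  r <- mean_center(m, "row")
  expect_equal(r$values[1, ], c(-1, 0, 1))
  expect_equal(r$values[2, ], c(-1, NA, 1))
  for (seed in 1:3) {
    sim <- simulate_expression_matrix(n_rows = 40, n_cols = 15,
                                      missing_frac = 0.2, seed = seed)
    for (ax in c("row", "col")) {
      ctr <- mean_center(sim$matrix, ax)
      mu <- if (ax == "row") rowMeans(ctr$values, na.rm = TRUE)
            else colMeans(ctr$values, na.rm = TRUE)
      expect_lt(max(abs(mu), na.rm = TRUE), 1e-12)
    }
  }
  # an all-missing row passes through untouched
  m2 <- labeled_matrix(matrix(c(NA, NA, 1, 3), 2, 2, byrow = TRUE))
  ctr2 <- mean_center(m2, "row")
  expect_true(all(is.na(ctr2$values[1, ])))
  expect_equal(ctr2$values[2, ], c(-1, 1))
})

test_that("transpose swaps labels and values and is an involution", {
  m <- labeled_matrix(matrix(1:6, 2, 3), c("r1", "r2"), c("c1", "c2", "c3"))
  t <- transpose_matrix(m)
  expect_equal(dim(t), c(3L, 2L))
  expect_equal(t$row_labels, m$col_labels)
  expect_equal(t$values[3, 1], m$values[1, 3])
  expect_true(lm_equal(transpose_matrix(t), m))
  one <- labeled_matrix(matrix(5), "r", "c")
  t1 <- transpose_matrix(one)
  expect_equal(t1$row_labels, "c")
  expect_equal(t1$values[1, 1], 5)
})

test_that("correlation matches the direct covariance/sd formula", {
  m <- labeled_matrix(matrix(c(1, 2, 3, 2, 4, 6, -1, -2, -3), 3, 3,
                             byrow = TRUE))
  r <- correlation_matrix(m, "row")
  expect_equal(r$values[1, 2], 1)
  expect_equal(r$values[1, 3], -1)
  expect_equal(diag(r$values), rep(1, 3))
  expect_equal(r$row_labels, r$col_labels)

  set.seed(42)
  x <- matrix(rnorm(150), 3, 50)
  x[sample(150, 10)] <- NA
  lm3 <- labeled_matrix(x)
  r2 <- correlation_matrix(lm3, "row")
  for (i in 1:2) for (j in (i + 1):3) {
    a <- x[i, ]; b <- x[j, ]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    expected <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_lt(abs(r2$values[i, j] - expected), 1e-10)
  }
  expect_warning(correlation_matrix(
    labeled_matrix(matrix(c(1, 1, 1, 1, 2, 3), 2, 3, byrow = TRUE)), "row"),
    "zero-variance")
})

test_that("replace_missing fills every hole and nothing else", {
  v <- matrix(c(1, NA, NA, 4, NA, 6), 2, 3)
  m <- labeled_matrix(v)
  r <- replace_missing(m, value = 0)
  expect_equal(sum(is.na(r$values)), 0L)
  expect_equal(sum(r$values == 0), 3L)
  expect_equal(r$values[!is.na(v)], v[!is.na(v)])
  full <- labeled_matrix(matrix(1:4, 2, 2))
  expect_true(lm_equal(replace_missing(full, value = 9), full))
})

test_that("missing-data filter retains the boundary and drops strictly above", {
  v <- rbind(c(1, 2, NA, NA),     # 50% -> retained
             c(1, NA, NA, NA),    # 75% -> removed
             c(1, 2, 3, 4))       # 0%
  m <- labeled_matrix(v, c("half", "mostly", "full"), paste0("c", 1:4))
  f <- filter_missing(m, "row", 50)
  expect_equal(f$row_labels, c("half", "full"))
  expect_true(lm_equal(filter_missing(m, "row", 100), m))
  all_na <- labeled_matrix(matrix(NA_real_, 2, 2))
  expect_error(filter_missing(all_na, "row", 10), "empty matrix")
  # survivors always satisfy the bound
  sim <- simulate_expression_matrix(n_rows = 60, n_cols = 10,
                                    missing_frac = 0.3, seed = 2)
  f2 <- filter_missing(sim$matrix, "row", 30)
  expect_true(all(rowMeans(is.na(f2$values)) * 100 <= 30))
})

test_that("top-SD filter keeps the most variable vectors in original order", {
  v <- rbind(c(1, 1, 1), c(0, 1, 2), c(-2, 0, 2))   # SDs 0, 1, 2
  m <- labeled_matrix(v, c("flat", "mid", "wide"), paste0("c", 1:3))
  f <- filter_top_sd(m, "row", 2)
  expect_equal(f$row_labels, c("mid", "wide"))
  expect_true(lm_equal(filter_top_sd(m, "row", 3), m))
  expect_true(lm_equal(filter_top_sd(m, "row", 10), m))

  sim <- simulate_expression_matrix(n_rows = 80, n_cols = 12,
                                    missing_frac = 0.1, seed = 3)
  f2 <- filter_top_sd(sim$matrix, "row", 20)
  sds <- apply(sim$matrix$values, 1, sd, na.rm = TRUE)
  kept <- sim$matrix$row_labels %in% f2$row_labels
  expect_gte(min(sds[kept]), max(sds[!kept]))
  # kept rows preserve their relative order
  expect_identical(f2$row_labels,
                   sim$matrix$row_labels[kept])
})

test_that("SD ties at the boundary go to the earlier row", {
  v <- rbind(c(0, 2), c(0, 2), c(0, 2))
  m <- labeled_matrix(v, c("first", "second", "third"), c("a", "b"))
  f <- filter_top_sd(m, "row", 2)
  expect_equal(f$row_labels, c("first", "second"))
})

test_that("sessions maintain working == replay(original, history)", {
  sim <- simulate_expression_matrix(n_rows = 50, n_cols = 10,
                                    missing_frac = 0.1, seed = 4)
  s <- matrix_session(sim$matrix)
  steps <- list(transform_step("threshold_na", cutoff = 1e-5),
                transform_step("log", base = 10),
                transform_step("mean_center_row"),
                transform_step("filter_missing_row", max_pct = 50),
                transform_step("filter_sd_row", keep_n = 20))
  for (st in steps) s <- apply_step(s, st)
  expect_length(s$history, 5L)
  expect_true(lm_equal(s$working, replay_steps(s$original, s$history)))

  # every undo prefix equals a fresh session with that prefix applied
  for (k in 0:5) {
    undone <- undo_to(s, k)
    fresh <- replay_steps(sim$matrix, steps[seq_len(k)])
    expect_true(lm_equal(undone$working, fresh))
    expect_length(undone$history, k)
  }
  expect_true(lm_equal(undo_to(s, 0)$working, sim$matrix))
  expect_error(undo_to(s, 9), "out of range")
})

test_that("a failing step leaves the session untouched", {
  m <- labeled_matrix(matrix(NA_real_, 2, 2))
  s <- matrix_session(m)
  expect_error(apply_step(s, transform_step("filter_missing_row", max_pct = 10)))
  expect_length(s$history, 0L)
  expect_true(lm_equal(s$working, m))
})

test_that("steps survive text serialization with identical replay", {
  steps <- list(transform_step("threshold_na", cutoff = 1e-5),
                transform_step("log", base = 10),
                transform_step("dedupe", axis = "col"),
                transform_step("filter_sd_row", keep_n = 15),
                transform_step("replace_missing", value = -0.125))
  lines <- serialize_steps(steps)
  expect_length(lines, 5L)
  reparsed <- parse_steps(lines)
  expect_identical(serialize_steps(reparsed), lines)
  sim <- simulate_expression_matrix(n_rows = 40, n_cols = 10, dup_cols = 2,
                                    seed = 5)
  expect_true(lm_equal(replay_steps(sim$matrix, steps),
                       replay_steps(sim$matrix, reparsed)))
  expect_error(transform_step("explode"), "unknown transform action")
})

test_that("summaries count cells, bins and advisories correctly", {
  m <- labeled_matrix(matrix(c(1, 2, 3, 4), 2, 2))
  s <- summarize_matrix(m, n_bins = 2)
  expect_equal(s$counts, c(2L, 2L))
  expect_equal(sum(s$counts), 4L)

  sim <- simulate_expression_matrix(n_rows = 50, n_cols = 10,
                                    missing_frac = 0.2, seed = 6)
  s2 <- summarize_matrix(sim$matrix)
  expect_equal(sum(s2$counts), sum(!is.na(sim$matrix$values)))

  big <- labeled_matrix(matrix(0, 10, 2), paste0("r", 1:10), c("a", "a"))
  s3 <- summarize_matrix(big, size_limit = 11)
  expect_true(any(grepl("size limit", s3$flags)))
  expect_true(any(grepl("duplicate column labels", s3$flags)))

  flat <- labeled_matrix(matrix(5, 3, 3))
  s4 <- summarize_matrix(flat)
  expect_equal(s4$counts, 9L)   # all-equal data collapses to one bin
})
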