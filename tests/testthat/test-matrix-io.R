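test_that("default region parses labels from row 0 and column 0", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,s1,s2", "g1,1.0,2.0", "g2,3.0,4.0"), f)
  m <- parse_matrix(f)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m$row_labels, c("g1", "g2"))
  expect_equal(m$col_labels, c("s1", "s2"))
  expect_equal(m$values, matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(m$n_invalid, 0L)
})

test_that("the same table parses identically from txt, csv and xlsx", {
  grid <- rbind(c("", "s1", "s2", "s3"),
                c("g1", "1.5", "n/a", "-2"),
                c("g2", "0.25", "1e3", "NA"),
                c("g3", "7", "8", "9.125"))
  files <- write_dialects(grid)
  parsed <- lapply(files, parse_matrix)
  expect_true(lm_equal(parsed$txt, parsed$csv))
  expect_true(lm_equal(parsed$txt, parsed$xlsx))
  expect_equal(parsed$csv$n_invalid, parsed$xlsx$n_invalid)
})

test_that("non-numeric tokens become missing and only unknown ones count as invalid", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("\ts1\ts2\ts3\ts4",
               "g1\t1\tn/a\tNaN\tnull",
               "g2\tNA\t\tbogus\tInf"), f)
  m <- parse_matrix(f)
  # n/a, bogus, Inf are invalid; NA/NaN/null/empty are recognized missing
  expect_equal(m$n_invalid, 3L)
  expect_equal(sum(is.na(m$values)), 7L)
  expect_equal(m$values[1, 1], 1)
})

test_that("an explicit region skips extra leading rows and columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("junk,junk,junk,junk",
               "note,id,s1,s2",
               "x,g1,1,2",
               "x,g2,3,4"), f)
  m <- parse_matrix(f, region_spec(label_row = 1, label_col = 1,
                                   data_origin = c(2, 2)))
  expect_equal(m$row_labels, c("g1", "g2"))
  expect_equal(m$col_labels, c("s1", "s2"))
  expect_equal(m$values, matrix(c(1, 3, 2, 4), 2, 2))
})

test_that("parse errors are specific", {
  expect_error(parse_matrix("nope_does_not_exist.txt"), "no such file")
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("x", f)
  expect_error(parse_matrix(f), "unsupported matrix format")
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines("onlylabel", g)
  expect_error(parse_matrix(g), "empty data region")
  expect_error(region_spec(label_row = 2, data_origin = c(1, 1)),
               "strictly below")
})

test_that("dedupe_labels renames later occurrences and is idempotent", {
  m <- labeled_matrix(matrix(0, 3, 3), paste0("r", 1:3), c("A", "A", "B"))
  d <- dedupe_labels(m, "col")
  expect_equal(d$col_labels, c("A", "A_2", "B"))
  expect_identical(dedupe_labels(d, "col")$col_labels, d$col_labels)

  m2 <- labeled_matrix(matrix(0, 1, 3), "r", c("A", "A", "A"))
  expect_equal(dedupe_labels(m2, "col")$col_labels, c("A", "A_2", "A_3"))

  # suffix collision with an existing label keeps incrementing
  m3 <- labeled_matrix(matrix(0, 1, 3), "r", c("A", "A", "A_2"))
  out <- dedupe_labels(m3, "col")$col_labels
  expect_false(anyDuplicated(out) > 0)
  expect_equal(out[1], "A")
  expect_equal(out[3], "A_2")

  m4 <- labeled_matrix(matrix(0, 3, 1), c("x", "y", "z"), "c")
  expect_identical(dedupe_labels(m4, "row")$row_labels, c("x", "y", "z"))
})

test_that("write_matrix round-trips exactly, including missing cells", {
  vals <- matrix(c(0.1, -3.25, 1/3, NA, 1e-7, 12345.678), 2, 3)
  m <- labeled_matrix(vals, c("g1", "g2"), c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".txt")
  write_matrix(m, f)
  m2 <- parse_matrix(f)
  expect_true(lm_equal(m, m2))
  # exactly one NA token in the data region
  body <- readLines(f)[-1]
  expect_equal(sum(unlist(strsplit(body, "\t"))[-c(1, 5)] == "NA"), 1L)
})

test_that("a 0-row matrix writes a header-only file and round-trips", {
  m <- labeled_matrix(matrix(numeric(0), 0, 2), character(0), c("s1", "s2"))
  f <- withr::local_tempfile(fileext = ".txt")
  write_matrix(m, f)
  expect_length(readLines(f), 1L)
  m2 <- parse_matrix(f)
  expect_true(lm_equal(m, m2))
})

test_that("round trip holds on random matrices with random missing patterns", {
  for (seed in 1:5) {
    sim <- simulate_expression_matrix(n_rows = 30, n_cols = 8,
                                      missing_frac = 0.15, seed = seed)
    f <- withr::local_tempfile(fileext = ".txt")
    write_matrix(sim$matrix, f)
    expect_true(lm_equal(sim$matrix, parse_matrix(f)))
  }
})
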