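labels3 <- c("s1", "s2", "s3")

test_that("discrete covariate files parse, restrict to matrix labels, and warn", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("s1\tSmoker", "s2\tNon-smoker"), f)
  cv <- parse_covariate(f, "col", "discrete", labels3, name = "smoking")
  expect_equal(cv$kind, "discrete")
  expect_equal(unname(cv$values[c("s1", "s2")]), c("Smoker", "Non-smoker"))
  expect_true(is.na(cv$values["s3"]))
  expect_length(unique(stats::na.omit(cv$values)), 2L)

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("s1,A", "s9,B"), g)
  expect_warning(cv2 <- parse_covariate(g, "col", "discrete", labels3),
                 "not in the matrix")
  expect_false("s9" %in% names(cv2$values)[!is.na(cv2$values)])

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(parse_covariate(empty, "col", "discrete", labels3), "empty")
})

test_that("continuous covariates parse numbers, auto-skip headers, flag junk", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("sample\tage", "s1\t63", "s2\t70"), f)
  cv <- parse_covariate(f, "col", "continuous", labels3, name = "age")
  expect_equal(unname(cv$values[c("s1", "s2")]), c(63, 70))
  expect_true(is.na(cv$values["s3"]))

  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("s1\t63", "s2\tunknown", "s3\t70"), g)
  expect_warning(cv2 <- parse_covariate(g, "col", "continuous", labels3),
                 "non-numeric")
  expect_true(is.na(cv2$values["s2"]))
  expect_equal(unname(cv2$values["s3"]), 70)
})

test_that("default discrete colors cycle the palette by first appearance", {
  pal <- default_palette()
  vals <- setNames(c("b", "a", "b", "c"), paste0("s", 1:4))
  cv <- default_colors(covariate("x", "col", "discrete", vals))
  expect_equal(names(cv$colors), c("b", "a", "c"))   # appearance order
  expect_equal(unname(cv$colors), pal$colors[1:3], ignore_attr = TRUE)
  expect_equal(attr(cv$colors, "missing_color"), "#FFFFFF")

  many <- setNames(paste0("cat", 1:9), paste0("s", 1:9))
  cv9 <- default_colors(covariate("y", "col", "discrete", many))
  expect_equal(unname(cv9$colors[9]), pal$colors[1])   # 9th wraps around
  # determinism
  cv_again <- default_colors(covariate("x", "col", "discrete", vals))
  expect_identical(cv_again$colors, cv$colors)
})

test_that("default continuous colors span observed min..max", {
  vals <- setNames(c(40, 80, NA, 60), paste0("s", 1:4))
  cv <- default_colors(covariate("age", "col", "continuous", vals))
  expect_s3_class(cv$colors, "color_map")
  expect_equal(cv$colors$breakpoints, c(40, 80))
})

test_that("reorder_bars permutes positions and rejects non-permutations", {
  a <- covariate("age", "col", "continuous", setNames(1:3, labels3), position = 1L)
  g <- covariate("gender", "col", "discrete",
                 setNames(c("F", "M", "F"), labels3), position = 2L)
  out <- reorder_bars(list(a, g), c(2, 1))
  expect_equal(vapply(out, function(x) x$name, ""), c("gender", "age"))
  expect_equal(vapply(out, function(x) x$position, 1L), 1:2)
  same <- reorder_bars(list(a, g), c(1, 2))
  expect_equal(vapply(same, function(x) x$name, ""), c("age", "gender"))
  expect_error(reorder_bars(list(a, g), c(1, 1)), "permutation")
  expect_error(reorder_bars(list(a, g), c(1)), "permutation")
})

test_that("embedded covariate rows/columns are lifted out of the grid", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,s1,s2,s3",
               "stage,II,III,II",
               "age,63,70,58",
               "g1,1,2,3",
               "g2,4,5,6"), f)
  out <- extract_embedded_covariates(f, covariate_rows = c(1, 2))
  expect_equal(dim(out$matrix), c(2L, 3L))
  expect_equal(out$matrix$row_labels, c("g1", "g2"))
  expect_length(out$covariates, 2L)
  stage <- out$covariates[[1]]
  expect_equal(stage$kind, "discrete")           # mixed strings
  expect_equal(unname(stage$values["s2"]), "III")
  age <- out$covariates[[2]]
  expect_equal(age$kind, "continuous")           # all numeric -> continuous
  expect_equal(unname(age$values["s1"]), 63)

  # no indices: plain parse, no covariates
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,s1,s2", "g1,1,2"), g)
  out2 <- extract_embedded_covariates(g)
  expect_length(out2$covariates, 0L)
  expect_equal(dim(out2$matrix), c(1L, 2L))

  # an index inside the data region is rejected
  expect_error(extract_embedded_covariates(f, covariate_rows = 3,
                                           region = region_spec(data_origin = c(3, 1))),
               "between the label row")
})

test_that("the palette store persists, seeds a default, and reloads", {
  store <- withr::local_tempfile(fileext = ".json")
  expect_false(file.exists(store))
  expect_true("okabe-ito" %in% list_palettes(store))
  save_palette(store, chm_palette("warm", c("#FF0000", "#FFAA00")))
  expect_setequal(list_palettes(store), c("okabe-ito", "warm"))
  p <- load_palette(store, "warm")
  expect_equal(p$colors, c("#FF0000", "#FFAA00"))
  expect_error(load_palette(store, "missing"), "no palette")
  expect_error(chm_palette("bad", "red"), "hex")
})
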