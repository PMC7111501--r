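# shared fixture builders; everything generated in code, nothing stored

tiny_matrix <- function() {
  labeled_matrix(matrix(c(1, 3, 2, 4), 2, 2), c("g1", "g2"), c("s1", "s2"))
}

# write the same logical grid in all three accepted dialects
write_dialects <- function(grid, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  txt <- file.path(dir, "m.txt")
  writeLines(apply(grid, 1, paste, collapse = "\t"), txt)
  csv <- file.path(dir, "m.csv")
  writeLines(apply(grid, 1, paste, collapse = ","), csv)
  xlsx <- file.path(dir, "m.xlsx")
  write_minimal_xlsx(grid, xlsx)
  c(txt = txt, csv = csv, xlsx = xlsx)
}

col_letters <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]; s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      n <- (n - 1) %/% 26
    }
    out[k] <- s
  }
  out
}

# minimal Office Open XML spreadsheet (single sheet, inline strings/numbers);
# enough for readers that understand the standard package structure
write_minimal_xlsx <- function(grid, path) {
  stage <- tempfile("xlsx_stage_")
  dir.create(file.path(stage, "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "worksheets"), recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE))
  xml_head <- "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>"
  writeLines(c(xml_head, paste0(
    "<Types xmlns=\"http://schemas.openxmlformats.org/package/2006/content-types\">",
    "<Default Extension=\"rels\" ContentType=\"application/vnd.openxmlformats-package.relationships+xml\"/>",
    "<Default Extension=\"xml\" ContentType=\"application/xml\"/>",
    "<Override PartName=\"/xl/workbook.xml\" ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml\"/>",
    "<Override PartName=\"/xl/worksheets/sheet1.xml\" ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml\"/>",
    "</Types>")), file.path(stage, "[Content_Types].xml"))
  writeLines(c(xml_head, paste0(
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    "<Relationship Id=\"rId1\" Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument\" Target=\"xl/workbook.xml\"/>",
    "</Relationships>")), file.path(stage, "_rels", ".rels"))
  writeLines(c(xml_head, paste0(
    "<workbook xmlns=\"http://schemas.openxmlformats.org/spreadsheetml/2006/main\" ",
    "xmlns:r=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships\">",
    "<sheets><sheet name=\"Sheet1\" sheetId=\"1\" r:id=\"rId1\"/></sheets></workbook>")),
    file.path(stage, "xl", "workbook.xml"))
  writeLines(c(xml_head, paste0(
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    "<Relationship Id=\"rId1\" Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet\" Target=\"worksheets/sheet1.xml\"/>",
    "</Relationships>")), file.path(stage, "xl", "_rels", "workbook.xml.rels"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  rows <- vapply(seq_len(nrow(grid)), function(r) {
    cells <- vapply(seq_len(ncol(grid)), function(cc) {
      ref <- paste0(col_letters(cc), r)
      v <- grid[r, cc]
      if (!nzchar(v)) return("")
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num) && grepl("^[-+0-9.eE]+$", v)) {
        sprintf("<c r=\"%s\"><v>%s</v></c>", ref, v)
      } else {
        sprintf("<c r=\"%s\" t=\"inlineStr\"><is><t>%s</t></is></c>", ref, esc(v))
      }
    }, "")
    sprintf("<row r=\"%d\">%s</row>", r, paste(cells, collapse = ""))
  }, "")
  writeLines(c(xml_head, paste0(
    "<worksheet xmlns=\"http://schemas.openxmlformats.org/spreadsheetml/2006/main\">",
    "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>")),
    file.path(stage, "xl", "worksheets", "sheet1.xml"))
  zip::zip(zipfile = file.path(normalizePath(dirname(path)), basename(path)),
           files = c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
                     "xl/_rels/workbook.xml.rels", "xl/worksheets/sheet1.xml"),
           root = stage, mode = "mirror", include_directories = FALSE)
  path
}

# a small but complete build (clustered axes, gaps, covariates) for
# round-trip / determinism / rendering tests
make_full_build <- function(seed = 1, n_rows = 18, n_cols = 12,
                            random_col = FALSE) {
  sim <- simulate_expression_matrix(n_rows = n_rows, n_cols = n_cols,
                                    n_row_clusters = 3, n_col_clusters = 3,
                                    missing_frac = 0.05, tiny_frac = 0,
                                    seed = seed)
  dir <- tempfile("fb")
  covs <- simulate_covariates(sim$matrix$col_labels, sim$col_cluster,
                              seed = seed)
  files <- write_fixture_files(dir, sim, covariates = covs, seed = seed)
  col_order <- if (random_col) order_spec("random", seed = seed + 100)
               else order_spec("cluster", "average", "manhattan")
  build <- build_heatmap(
    files[["matrix"]],
    transforms = list(transform_step("log", base = 2)),
    row_order = order_spec("cluster", "ward", "euclidean"),
    col_order = col_order,
    covariate_files = list(
      group = list(path = files[["group"]], axis = "col", kind = "discrete"),
      age = list(path = files[["age"]], axis = "col", kind = "continuous")),
    spec = heat_map_spec(name = "fixture map",
                         row_gaps = c(5L), col_gaps = c(3L, 7L),
                         top_items = "gene_0001"))
  list(build = build, files = files, sim = sim)
}
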