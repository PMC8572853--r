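test_that("MTX coordinate format reads exactly the declared nonzeros", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "3 2 1"), file.path(dir, "m.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "f.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "b.tsv"))
  em <- read_matrix(file.path(dir, "m.mtx"), file.path(dir, "f.tsv"),
                    file.path(dir, "b.tsv"))
  expect_equal(em$layer, "raw")
  expect_equal(em$gene_ids, c("gA", "gB", "gC"))
  expect_equal(em$cell_ids, c("c1", "c2"))
  expect_equal(as.matrix(em$values),
               matrix(c(5, 0, 0, 0, 0, 1), 3, 2,
                      dimnames = list(c("gA", "gB", "gC"), c("c1", "c2"))))
})

test_that("matrix write/read round-trips ids and values losslessly", {
  withr::with_seed(1, {
    v <- matrix(rpois(60, 1.5), 10, 6)
  })
  em <- expr_matrix(v, sprintf("g%02d", 1:10), sprintf("c%02d", 1:6), layer = "raw")
  dir <- withr::local_tempdir()
  write_matrix(em, dir)
  back <- read_matrix(file.path(dir, "matrix.mtx"), file.path(dir, "features.tsv"),
                      file.path(dir, "barcodes.tsv"))
  expect_identical(back$gene_ids, em$gene_ids)
  expect_identical(back$cell_ids, em$cell_ids)
  expect_equal(as.matrix(back$values), as.matrix(em$values))
  # second round trip is bit-stable
  dir2 <- withr::local_tempdir()
  write_matrix(back, dir2)
  expect_identical(readLines(file.path(dir, "matrix.mtx")),
                   readLines(file.path(dir2, "matrix.mtx")))
})

test_that("dimension mismatches raise errors naming the offending file", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 1", "1 1 4"), file.path(dir, "m.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "f.tsv"))
  writeLines(c("c1", "c2", "c3"), file.path(dir, "b.tsv"))
  expect_error(read_matrix(file.path(dir, "m.mtx"), file.path(dir, "f.tsv"),
                           file.path(dir, "b.tsv")),
               "b.tsv", fixed = TRUE)
  writeLines(c("gA", "gB"), file.path(dir, "f2.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "b2.tsv"))
  expect_error(read_matrix(file.path(dir, "m.mtx"), file.path(dir, "f2.tsv"),
                           file.path(dir, "b2.tsv")),
               "f2.tsv", fixed = TRUE)
})

test_that("invalid expression matrices are rejected", {
  expect_error(expr_matrix(matrix(-1, 1, 1), "g", "c", layer = "raw"),
               "non-negative")
  expect_error(expr_matrix(matrix(1.5, 1, 1), "g", "c", layer = "raw"),
               "integer")
  expect_error(expr_matrix(matrix(1, 2, 1), c("g", "g"), "c", layer = "raw"),
               "duplicate gene_ids")
  expect_silent(expr_matrix(matrix(1.5, 1, 1), "g", "c", layer = "normalized"))
})

test_that("gene-set reader deduplicates, preserves order, flags empties", {
  f <- withr::local_tempfile(lines = c("M2\tMrc1\tCd163",
                                       "dup\tA\tA",
                                       "big\tZ\tY\tX"))
  sets <- read_gene_sets(f)
  expect_named(sets, c("M2", "dup", "big"))
  expect_equal(sets$M2$genes, c("Mrc1", "Cd163"))
  expect_equal(sets$dup$genes, "A")
  expect_equal(sets$big$genes, c("Z", "Y", "X"))

  empty <- withr::local_tempfile(lines = character(0))
  expect_warning(out <- read_gene_sets(empty), "no records")
  expect_length(out, 0)

  bad <- withr::local_tempfile(lines = "lonely")
  expect_error(read_gene_sets(bad), "lonely")
  # GMT layout with a description column
  gmt <- withr::local_tempfile(lines = "S1\tsome description\tA\tB")
  expect_equal(read_gene_sets(gmt, description = TRUE)$S1$genes, c("A", "B"))
})

test_that("gene-set write/read round-trips", {
  sets <- list(gene_signature("a", c("X", "Y")), gene_signature("b", "Z"))
  f <- withr::local_tempfile()
  write_gene_sets(sets, f)
  back <- read_gene_sets(f)
  expect_equal(back$a$genes, c("X", "Y"))
  expect_equal(back$b$genes, "Z")
})

test_that("annotated CSV round-trips values and records provenance", {
  df <- data.frame(cell_id = c("c1", "c2"),
                   score = c(0.12345678901234, -3.1e-7))
  f <- withr::local_tempfile()
  write_scores(df, f, seed = 77, config_hash = "abc123")
  lines <- readLines(f)
  expect_match(lines[1], "^# seed: 77$")
  expect_match(lines[2], "^# config: abc123$")
  back <- read_annotated_csv(f)
  expect_equal(nrow(back), 2)
  expect_equal(back$score, df$score, tolerance = 1e-12)

  # empty table -> header-only CSV
  f2 <- withr::local_tempfile()
  write_cell_table(df[0, ], f2)
  expect_equal(nrow(read_annotated_csv(f2)), 0)
  expect_error(write_cell_table(df, file.path(tempdir(), "no/such/dir/x.csv")),
               "cannot open")
})

test_that("substream seeds are deterministic, distinct and within range", {
  s1 <- substream_seed(42, "score")
  expect_identical(s1, substream_seed(42, "score"))
  keys <- c("simulate", "qc", "cluster", "score", "lrscreen")
  vals <- vapply(keys, substream_seed, integer(1), seed = 42)
  expect_equal(anyDuplicated(vals), 0L)
  expect_true(all(vals >= 0 & vals < 2^31))
})
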