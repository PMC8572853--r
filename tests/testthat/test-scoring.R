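test_that("bin partition follows the rank-order remainder rule", {
  em <- toy_norm_matrix(250, 10)
  b <- assign_bins(em, 25)
  expect_true(all(lengths(b$bin_genes) == 10))
  em2 <- toy_norm_matrix(252, 10)
  b2 <- assign_bins(em2, 25)
  expect_equal(unname(lengths(b2$bin_genes)), c(11, 11, rep(10, 23)))
  # highest-mean gene sits in the top bin; bin means are non-decreasing
  top <- names(which.max(b2$means))
  expect_equal(b2$bins[[top]], 25L)
  bin_means <- vapply(b2$bin_genes, function(g) mean(b2$means[g]), numeric(1))
  expect_true(all(diff(bin_means) >= 0))
  expect_error(assign_bins(em, 300), "exceeds")
})

test_that("control sampling is exhaustive, seeded and pooled with multiplicity", {
  em <- toy_norm_matrix(202, 12)
  b <- assign_bins(em, 2)  # two bins of 101
  target <- b$bin_genes[["1"]][5]
  cs <- sample_controls(b, gene_signature("s", target), n_ctrl = 100, seed = 1)
  expect_setequal(cs$controls[[target]], setdiff(b$bin_genes[["1"]], target))
  expect_length(cs$pooled, 100)
  # seeds: same seed identical, different seed different (large bin)
  b25 <- assign_bins(toy_norm_matrix(2000, 5, seed = 7), 4)
  sig <- gene_signature("t", b25$bin_genes[["2"]][1:3])
  c1 <- sample_controls(b25, sig, n_ctrl = 50, seed = 3)
  c2 <- sample_controls(b25, sig, n_ctrl = 50, seed = 3)
  c3 <- sample_controls(b25, sig, n_ctrl = 50, seed = 4)
  expect_identical(c1$pooled, c2$pooled)
  expect_false(identical(c1$pooled, c3$pooled))
  expect_length(c1$pooled, 150)  # 3 targets x 50, multiset pooling
  expect_true(all(vapply(c1$controls, function(g) !any(g %in% sig$genes), logical(1))))
})

test_that("missing signature genes warn; fully absent signatures error", {
  em <- toy_norm_matrix(100, 8)
  b <- assign_bins(em, 10)
  expect_warning(cs <- sample_controls(b, gene_signature("s", c("g001", "nope")),
                                       seed = 1), "absent")
  expect_equal(cs$targets, "g001")
  expect_error(suppressWarnings(
    sample_controls(b, gene_signature("s", "nope"), seed = 1)), "no genes present")
  # a bin fully consumed by the signature cannot provide controls
  em2 <- toy_norm_matrix(20, 6)
  b2 <- assign_bins(em2, 2)
  whole_bin <- gene_signature("all", b2$bin_genes[["1"]])
  expect_error(sample_controls(b2, whole_bin, seed = 1), "bin 1")
})

test_that("flat cells score exactly zero for any signature", {
  # every gene has the same value within each cell
  v <- matrix(rep(seq(0.1, 1.0, length.out = 9), each = 50), 50, 9)
  em <- expr_matrix(v, sprintf("g%02d", 1:50), sprintf("c%02d", 1:9),
                    layer = "normalized")
  b <- assign_bins(em, 5)
  withr::with_seed(1, sig <- gene_signature("s", sample(em$gene_ids, 8)))
  cs <- score_cells(em, sig, b, n_ctrl = 5, seed = 2)
  expect_equal(unname(cs), rep(0, 9))
})

test_that("exhaustive controls reproduce an independent direct computation", {
  em <- toy_norm_matrix(200, 30, seed = 12)
  b <- assign_bins(em, 10)
  withr::with_seed(13, sig <- gene_signature("s", sample(em$gene_ids, 12)))
  cs <- score_cells(em, sig, b, n_ctrl = 10000, seed = 3)
  v <- as.matrix(em$values)
  oracle <- vapply(seq_len(30), function(ci) {
    tm <- mean(v[match(sig$genes, em$gene_ids), ci])
    pool <- unlist(lapply(sig$genes, function(g) {
      setdiff(b$bin_genes[[as.character(b$bins[[g]])]], sig$genes)
    }))
    tm - mean(v[match(pool, em$gene_ids), ci])
  }, numeric(1))
  expect_equal(unname(cs), oracle, tolerance = 1e-12)
})

test_that("scores are location-invariant and seed-reproducible", {
  em <- toy_norm_matrix(150, 12)
  b <- assign_bins(em, 10)
  withr::with_seed(5, sig <- gene_signature("s", sample(em$gene_ids, 10)))
  cs1 <- score_cells(em, sig, b, n_ctrl = 8, seed = 9)
  cs2 <- score_cells(em, sig, b, n_ctrl = 8, seed = 9)
  expect_identical(cs1, cs2)
  # add a constant to every gene of cell 3: its score is unchanged
  v <- as.matrix(em$values)
  v[, 3] <- v[, 3] + 7
  em2 <- expr_matrix(v, em$gene_ids, em$cell_ids, layer = "normalized")
  cs3 <- score_cells(em2, sig, b, n_ctrl = 8, seed = 9)
  expect_equal(cs3[[3]], cs1[[3]], tolerance = 1e-12)
})

test_that("score_many columns equal solo runs on per-signature substreams", {
  em <- toy_norm_matrix(300, 20)
  b <- assign_bins(em, 10)
  withr::with_seed(6, {
    sigs <- list(gene_signature("alpha", sample(em$gene_ids, 10)),
                 gene_signature("beta", sample(em$gene_ids, 10)))
  })
  tab <- score_many(em, sigs, b, n_ctrl = 10, seed = 100)
  expect_named(tab, c("cell_id", "alpha", "beta"))
  solo <- score_cells(em, sigs[[2]], b, n_ctrl = 10,
                      seed = substream_seed(100, "beta"))
  expect_equal(tab$beta, unname(solo))
  dup <- list(sigs[[1]], sigs[[1]])
  expect_error(score_many(em, dup, b, seed = 1), "duplicate")
})

test_that("M2-polarized macrophages score higher on M2 than M1", {
  cfg <- small_config(250, 250)
  ds <- generate_dataset(cfg, seed = 14)
  nm <- normalize_total(ds$matrix)
  b <- assign_bins(nm)
  tab <- score_many(nm, program_signatures(cfg, c("M1", "M2")), b, seed = 15)
  mac <- ds$truth$cells$truth_type == "macrophage"
  expect_gt(mean(tab$M2[mac]), mean(tab$M1[mac]))
})

test_that("random signatures on null data have near-zero mean scores", {
  # the mean score carries a control-matching residual that does not shrink
  # with cell count; the bound here is the absolute bias, small against the
  # planted effects the score is used to detect
  for (s in 1:4) {
    cfg <- null_config(250, 250, n_genes = 800, seed = s)
    ds <- generate_dataset(cfg)
    nm <- normalize_total(ds$matrix)
    b <- assign_bins(nm)
    withr::with_seed(100 + s, sig <- gene_signature("rand", sample(cfg$gene_ids, 50)))
    cs <- score_cells(nm, sig, b, seed = 200 + s)
    expect_lt(abs(mean(cs)), 0.05)
  }
})
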