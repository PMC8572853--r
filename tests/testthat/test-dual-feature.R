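test_that("marker-positive extraction applies the count threshold", {
  v <- matrix(0L, 2, 3)
  v[1, ] <- c(0L, 1L, 5L)
  em <- expr_matrix(v, c("Cd68", "gB"), c("c1", "c2", "c3"), layer = "raw")
  pos <- extract_positive_cells(em, "Cd68", min_count = 1)
  expect_equal(pos$cell_ids, c("c2", "c3"))
  expect_equal(extract_positive_cells(em, "Cd68", min_count = 0)$cell_ids,
               c("c1", "c2", "c3"))
  expect_warning(none <- extract_positive_cells(em, "Cd68", min_count = 10),
                 "no cells")
  expect_length(none$cell_ids, 0)
  expect_error(extract_positive_cells(em, "Cd86"), "near matches.*Cd68")
})

test_that("doublet heuristic guards degenerate spreads and honours k", {
  tab <- data.frame(cell_id = paste0("c", 1:10), n_features = rep(500L, 10),
                    condition = rep(c("normal", "inflamed"), 5))
  expect_false(any(flag_doublets_heuristic(tab)$doublet))  # MAD = 0
  tab2 <- tab
  tab2$n_features <- c(100L, 120L, 130L, 110L, 125L, 115L, 105L, 135L, 128L, 5000L)
  expect_false(any(flag_doublets_heuristic(tab2, k = Inf)$doublet))
  expect_true(flag_doublets_heuristic(tab2, k = 3)$doublet[10])
})

test_that("heuristic flags planted doublets above chance and above dual cells", {
  # operating point verified on the generator: k = 2 keeps the false-positive
  # rate well under 5% while catching a usable share of thinned doublets
  rec <- fpr <- dual_rate <- numeric(0)
  for (s in 1:3) {
    ds <- generate_dataset(default_study_config(), seed = s)
    ct <- flag_doublets_heuristic(ds$cells, k = 2)
    tr <- ds$truth$cells
    rec <- c(rec, mean(ct$doublet[tr$doublet]))
    fpr <- c(fpr, mean(ct$doublet[!tr$doublet]))
    dual_rate <- c(dual_rate, mean(ct$doublet[tr$dual]))
  }
  expect_lte(mean(fpr), 0.05)
  expect_gte(mean(rec), 0.10)
  # planted doublets are flagged at a higher rate than planted dual-feature
  # cells: depth, not co-expression, is what the heuristic keys on
  expect_gt(mean(rec), mean(dual_rate))
})

test_that("score correlation handles affine, inverted and degenerate inputs", {
  withr::with_seed(1, a <- stats::rnorm(50))
  expect_equal(correlate_scores(a, 2 * a + 1)$r, 1, tolerance = 1e-12)
  expect_equal(correlate_scores(a, -a)$r, -1, tolerance = 1e-12)
  deg <- correlate_scores(a, rep(1, 50))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$r))
  withr::with_seed(2, {
    x <- stats::rnorm(10000)
    y <- stats::rnorm(10000)
  })
  expect_lt(abs(correlate_scores(x, y)$r), 0.05)
  expect_error(correlate_scores(1:2, 1:2), "at least 3")
})

test_that("dual-feature calls use strict thresholds and record them", {
  lin <- stats::setNames(c(0.8, 0.2, 0.9, 0.1), paste0("c", 1:4))
  pha <- stats::setNames(c(0.6, 0.9, 0.2, 0.1), paste0("c", 1:4))
  calls <- call_dual_feature(lin, pha, t_lineage = 0.2, t_phago = 0.2)
  expect_equal(calls$dual, c(TRUE, FALSE, FALSE, FALSE))  # boundary not flagged
  expect_equal(attr(calls, "t_lineage"), 0.2)
  # default thresholds: 75th percentiles of each score
  withr::with_seed(3, {
    l2 <- stats::rnorm(200)
    p2 <- stats::rnorm(200)
  })
  c2 <- call_dual_feature(l2, p2)
  expect_equal(attr(c2, "t_phago"), stats::quantile(p2, 0.75, names = FALSE))
  expect_equal(c2$dual, l2 > stats::quantile(l2, 0.75) & p2 > stats::quantile(p2, 0.75))
})

test_that("group score comparison is symmetric and powered", {
  withr::with_seed(4, x <- stats::rnorm(100))
  g <- rep(c("A", "B"), each = 50)
  same <- compare_score_distributions(c(x[1:50], x[1:50]), g)
  expect_gt(same$p, 0.9)
  shifted <- compare_score_distributions(c(x[1:50], x[51:100] + 5 * stats::sd(x)), g)
  expect_lt(shifted$p, 1e-10)
  flipped <- compare_score_distributions(c(x[51:100] + 5 * stats::sd(x), x[1:50]),
                                         rev(g))
  expect_equal(shifted$p, flipped$p)
  expect_named(shifted$medians, c("A", "B"))
  expect_error(compare_score_distributions(x, rep("A", 100)), "two groups")
  expect_error(compare_score_distributions(x[1:5], c("A", "A", "A", "B", "B")),
               "at least 3")
})

test_that("composition tables are per-condition fractions that conserve cells", {
  tab <- data.frame(cell_id = paste0("c", 1:10),
                    condition = rep("normal", 10),
                    cluster = c(rep("C0", 6), rep("C1", 4)))
  pr <- proportions_by_condition(tab)
  expect_equal(pr$fraction[match(c("C0", "C1"), pr$label)], c(0.6, 0.4))
  expect_equal(sum(pr$n), nrow(tab))
  # unlabeled cells surface as an explicit row
  tab$cluster[1] <- NA
  pr2 <- proportions_by_condition(tab)
  expect_true("unassigned" %in% pr2$label)
  expect_equal(sum(pr2$fraction), 1, tolerance = 1e-9)
})

test_that("generated data show the immune-infiltration composition shift", {
  ds <- generate_dataset(small_config(300, 300), seed = 23)
  tab <- cbind(ds$cells, type = ds$truth$cells$host_type)
  pr <- proportions_by_condition(tab, by = "type")
  f <- function(cond) sum(pr$fraction[pr$condition == cond &
                                        pr$label %in% c("neutrophil", "macrophage")])
  expect_gt(f("inflamed"), f("normal"))
  for (cond in c("normal", "inflamed")) {
    expect_equal(sum(pr$fraction[pr$condition == cond]), 1, tolerance = 1e-9)
  }
  expect_equal(sum(pr$n), nrow(tab))
})
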