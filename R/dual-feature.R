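#' Extract cells positive for a marker gene
#'
#' Subsets the matrix (and cell table) to cells whose raw count of the marker
#' gene is at least `min_count`. The default marker is `Cd68`, the pan-
#' phagocyte marker used to pull out candidate professional and
#' non-professional phagocytes.
#'
#' @param matrix Raw [expr_matrix()] (or a normalized one carrying its raw
#'   companion layer).
#' @param gene Marker gene id (default `"Cd68"`).
#' @param min_count Minimum raw count to call a cell positive (default 1;
#'   `min_count = 0` returns every cell).
#' @param cell_table Optional per-cell table subset alongside.
#' @return List with `matrix` (subset, same layer as input), `cells` (subset
#'   table or `NULL`) and `cell_ids`.
#' @export
extract_positive_cells <- function(matrix, gene = "Cd68", min_count = 1,
                                   cell_table = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (!gene %in% matrix$gene_ids) {
    near <- agrep(gene, matrix$gene_ids, max.distance = 0.25, value = TRUE,
                  ignore.case = TRUE)
    stop("gene '", gene, "' not found in matrix",
         if (length(near)) paste0("; near matches: ",
                                  paste(utils::head(near, 5), collapse = ", ")),
         call. = FALSE)
  }
  raw <- if (matrix$layer == "raw") matrix$values else matrix$raw
  if (is.null(raw)) stop("raw counts unavailable on this matrix", call. = FALSE)
  cnt <- raw[match(gene, matrix$gene_ids), ]
  keep <- which(cnt >= min_count)
  if (length(keep) == 0L) {
    warning("no cells positive for ", gene, "; downstream stages cannot run",
            call. = FALSE)
  }
  cells <- NULL
  if (!is.null(cell_table)) {
    cells <- cell_table[match(matrix$cell_ids[keep], cell_table$cell_id), ,
                        drop = FALSE]
    rownames(cells) <- NULL
  }
  list(matrix = em_subset(matrix, cells = keep), cells = cells,
       cell_ids = matrix$cell_ids[keep])
}

#' Heuristic doublet flagging from feature counts
#'
#' Flags a cell as a putative doublet when its unique feature count strictly
#' exceeds `median + k * MAD` of the feature counts within its condition
#' (MAD is the scaled median absolute deviation, [stats::mad()]). With a
#' constant feature count the MAD is zero and the strict inequality flags
#' nothing.
#'
#' @param cell_table Per-cell table with `n_features` (and optionally
#'   `condition`; without it all cells form one group).
#' @param k MAD multiplier (default 3; `k = Inf` flags nothing).
#' @return The table with a logical `doublet` column added/overwritten.
#' @export
flag_doublets_heuristic <- function(cell_table, k = 3) {
  stopifnot("n_features" %in% names(cell_table))
  grp <- if ("condition" %in% names(cell_table)) cell_table$condition else
    rep("all", nrow(cell_table))
  flag <- logical(nrow(cell_table))
  for (g in unique(grp)) {
    i <- grp == g
    nf <- cell_table$n_features[i]
    thr <- stats::median(nf) + k * stats::mad(nf)
    flag[i] <- nf > thr
  }
  cell_table$doublet <- flag
  cell_table
}

#' Pearson correlation between two score vectors
#'
#' @param scores_a,scores_b Aligned numeric vectors, `n >= 3`.
#' @return List with `r`, `p` (two-sided, t transform), `n`, and `degenerate`
#'   (`TRUE`, with an `NA` correlation, when either vector has zero variance).
#' @export
correlate_scores <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  n <- length(scores_a)
  if (n < 3) stop("need at least 3 paired scores", call. = FALSE)
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- stats::cor.test(scores_a, scores_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, degenerate = FALSE)
}

#' Call dual-feature cells from a lineage and a phagocytosis score
#'
#' A cell is dual-feature when its lineage score AND its phagocytosis score
#' are strictly above their thresholds. By default each threshold is the
#' within-dataset 75th percentile of the corresponding score, an explicit,
#' tunable stand-in for the by-eye score-scatter rule of exploratory
#' analyses.
#'
#' @param lineage_scores,phago_scores Aligned named numeric vectors.
#' @param t_lineage,t_phago Thresholds; `NULL` (default) uses the 75th
#'   percentile of the respective score.
#' @param lineage Name recorded for the lineage signature.
#' @return Data frame `cell_id`, `lineage`, `lineage_score`, `phago_score`,
#'   `dual`, with thresholds in attributes `t_lineage`, `t_phago`.
#' @export
call_dual_feature <- function(lineage_scores, phago_scores,
                              t_lineage = NULL, t_phago = NULL,
                              lineage = "lineage") {
  stopifnot(length(lineage_scores) == length(phago_scores))
  if (is.null(t_lineage)) t_lineage <- stats::quantile(lineage_scores, 0.75, names = FALSE)
  if (is.null(t_phago)) t_phago <- stats::quantile(phago_scores, 0.75, names = FALSE)
  stopifnot(is.finite(t_lineage), is.finite(t_phago))
  ids <- names(lineage_scores)
  if (is.null(ids)) ids <- as.character(seq_along(lineage_scores))
  out <- data.frame(cell_id = ids,
                    lineage = lineage,
                    lineage_score = unname(lineage_scores),
                    phago_score = unname(phago_scores),
                    dual = unname(lineage_scores > t_lineage & phago_scores > t_phago),
                    stringsAsFactors = FALSE)
  attr(out, "t_lineage") <- t_lineage
  attr(out, "t_phago") <- t_phago
  out
}

#' Compare score distributions between two groups
#'
#' Two-sided Wilcoxon rank-sum test of the scores between exactly two groups,
#' with per-group medians reported.
#'
#' @param scores Numeric vector.
#' @param group_labels Vector with exactly two distinct values, each group
#'   holding at least 3 cells.
#' @return List with `statistic` (rank-sum W), `p`, `medians` (named),
#'   `groups`.
#' @export
compare_score_distributions <- function(scores, group_labels) {
  stopifnot(length(scores) == length(group_labels))
  groups <- unique(group_labels)
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  a <- scores[group_labels == groups[1]]
  b <- scores[group_labels == groups[2]]
  if (length(a) < 3 || length(b) < 3) stop("each group needs at least 3 cells", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  med <- stats::setNames(c(stats::median(a), stats::median(b)), as.character(groups))
  list(statistic = unname(wt$statistic), p = wt$p.value, medians = med,
       groups = as.character(groups))
}

#' Cluster (or cell-type) composition by condition
#'
#' Counts cells per label and condition and converts them to within-condition
#' fractions (fractions sum to one within each condition). Unlabeled cells
#' are counted under an explicit `"unassigned"` row.
#'
#' @param cell_table Per-cell table with `condition` and the label column.
#' @param by Name of the label column (default `"cluster"`).
#' @return Data frame `label`, `condition`, `n`, `fraction`.
#' @export
proportions_by_condition <- function(cell_table, by = "cluster") {
  stopifnot(all(c("condition", by) %in% names(cell_table)))
  lab <- as.character(cell_table[[by]])
  lab[is.na(lab) | !nzchar(lab)] <- "unassigned"
  conds <- unique(as.character(cell_table$condition))
  if (length(conds) == 0L) warning("no conditions present", call. = FALSE)
  out <- do.call(rbind, lapply(conds, function(cond) {
    i <- cell_table$condition == cond
    if (!any(i)) {
      warning("condition '", cond, "' has no cells", call. = FALSE)
      return(NULL)
    }
    tab <- table(lab[i])
    data.frame(label = names(tab), condition = cond, n = as.integer(tab),
               fraction = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
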