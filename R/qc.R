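#' Per-cell quality-control statistics
#'
#' Computes the number of detected genes, the total raw counts and the
#' mitochondrial count fraction for every cell. Mitochondrial genes are
#' identified by gene-symbol prefix (default `"Mt-"`, the rat convention,
#' matched case-insensitively). An all-zero cell gets `mito_fraction = 0` and
#' is reported via a message.
#'
#' @param matrix A raw-layer [expr_matrix()].
#' @param cell_table Optional existing per-cell table to extend (must contain
#'   `cell_id`); by default a fresh table is built.
#' @param mito_prefix Gene-symbol prefix identifying mitochondrial genes.
#' @return Data frame with columns `cell_id`, `n_features`, `total_counts`,
#'   `mito_fraction` (plus any columns of `cell_table`).
#' @export
compute_cell_qc <- function(matrix, cell_table = NULL, mito_prefix = "Mt-") {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "raw") stop("QC statistics are defined on the raw layer", call. = FALSE)
  v <- matrix$values
  n_features <- Matrix::colSums(v > 0)
  total_counts <- Matrix::colSums(v)
  mito <- grepl(paste0("^", mito_prefix), matrix$gene_ids, ignore.case = TRUE)
  mito_counts <- if (any(mito)) Matrix::colSums(v[mito, , drop = FALSE]) else
    numeric(ncol(v))
  mito_fraction <- ifelse(total_counts > 0, mito_counts / total_counts, 0)
  if (any(total_counts == 0)) {
    message(sum(total_counts == 0), " all-zero cell(s) present; mito_fraction set to 0")
  }
  qc <- data.frame(cell_id = matrix$cell_ids,
                   n_features = as.integer(n_features),
                   total_counts = as.numeric(total_counts),
                   mito_fraction = as.numeric(mito_fraction),
                   stringsAsFactors = FALSE)
  if (!is.null(cell_table)) {
    stopifnot("cell_id" %in% names(cell_table))
    keep <- cell_table[, setdiff(names(cell_table), names(qc)[-1]), drop = FALSE]
    qc <- merge(keep, qc, by = "cell_id", sort = FALSE)
    qc <- qc[match(matrix$cell_ids, qc$cell_id), , drop = FALSE]
    rownames(qc) <- NULL
  }
  qc
}

#' QC threshold set
#'
#' @param min_features,max_features Feature-count bounds; a cell is removed if
#'   its unique feature count is strictly below `min_features` or strictly
#'   above `max_features`.
#' @param max_mito_fraction A cell is removed if its mitochondrial fraction is
#'   strictly above this limit.
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features, max_features, max_mito_fraction) {
  stopifnot(min_features > 0, max_features > 0, min_features < max_features,
            max_mito_fraction > 0, max_mito_fraction <= 1)
  structure(list(min_features = min_features, max_features = max_features,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Condition-specific QC threshold presets
#'
#' Per-condition filter presets for the two tissue states: inflamed mucosa keeps cells with
#' 200 <= features <= 4000 and mitochondrial fraction <= 20%; normal mucosa
#' keeps 200 <= features <= 3000 and mitochondrial fraction <= 40%. All
#' inequalities used for removal are strict, so boundary cells are kept.
#'
#' @param condition `"inflamed"` or `"normal"`.
#' @return A [qc_thresholds()] object.
#' @export
qc_preset <- function(condition = c("inflamed", "normal")) {
  condition <- match.arg(condition)
  switch(condition,
         inflamed = qc_thresholds(200, 4000, 0.20),
         normal   = qc_thresholds(200, 3000, 0.40))
}

#' Filter cells on QC thresholds
#'
#' A cell is removed iff `n_features < min_features` OR
#' `n_features > max_features` OR `mito_fraction > max_mito_fraction`
#' (strict inequalities; boundary cells are kept). The removal report
#' attributes each removed cell to a single reason with precedence
#' low-features, high-features, then mito, so reason counts partition the
#' removed set.
#'
#' @param matrix Raw [expr_matrix()].
#' @param cell_table Per-cell table with QC fields (see [compute_cell_qc()]).
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `matrix` and `cells` (the retained subset) and `report`
#'   (data frame of removal counts by reason).
#' @export
filter_cells <- function(matrix, cell_table, thresholds) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (!inherits(thresholds, "qc_thresholds")) {
    stop("thresholds must be a qc_thresholds object", call. = FALSE)
  }
  need <- c("cell_id", "n_features", "mito_fraction")
  if (!all(need %in% names(cell_table))) {
    stop("cell_table lacks QC fields; run compute_cell_qc() first", call. = FALSE)
  }
  tab <- cell_table[match(matrix$cell_ids, cell_table$cell_id), , drop = FALSE]
  low  <- tab$n_features < thresholds$min_features
  high <- tab$n_features > thresholds$max_features
  mito <- tab$mito_fraction > thresholds$max_mito_fraction
  removed <- low | high | mito
  reason <- rep(NA_character_, nrow(tab))
  reason[mito] <- "high_mito"
  reason[high] <- "high_features"
  reason[low]  <- "low_features"
  report <- data.frame(
    reason = c("low_features", "high_features", "high_mito", "total_removed"),
    n = c(sum(reason == "low_features", na.rm = TRUE),
          sum(reason == "high_features", na.rm = TRUE),
          sum(reason == "high_mito", na.rm = TRUE),
          sum(removed)),
    stringsAsFactors = FALSE)
  keep <- which(!removed)
  cells <- tab[keep, , drop = FALSE]
  rownames(cells) <- NULL
  list(matrix = em_subset(matrix, cells = keep), cells = cells, report = report)
}

#' Total-count log normalization
#'
#' Each value becomes `ln(1 + scale * count / total_counts_of_cell)`: counts
#' are scaled to a common library size and log1p-transformed. The raw counts
#' are retained alongside on the returned object. Zero counts map to zero
#' exactly, so the sparsity pattern is preserved.
#'
#' @param matrix Raw [expr_matrix()] with no all-zero cells (filter first).
#' @param scale Common library-size scale factor (default `1e4`).
#' @return An [expr_matrix()] with `layer = "normalized"`.
#' @export
normalize_total <- function(matrix, scale = 1e4) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "raw") stop("normalize_total expects the raw layer", call. = FALSE)
  v <- matrix$values
  totals <- Matrix::colSums(v)
  if (any(totals == 0)) {
    stop("all-zero cells present; run QC filtering before normalization", call. = FALSE)
  }
  norm <- v
  if (length(norm@x)) {
    col_of <- rep.int(seq_len(ncol(norm)), diff(norm@p))
    norm@x <- log1p(scale * norm@x / totals[col_of])
  }
  expr_matrix(norm, matrix$gene_ids, matrix$cell_ids, layer = "normalized",
              raw = v)
}
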