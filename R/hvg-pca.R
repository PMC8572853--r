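#' Select highly variable genes by standardized variance
#'
#' Genes are ranked by the ratio of their observed variance (of normalized
#' expression) to the variance expected at their mean, taken from a loess fit
#' of log10 variance against log10 mean across all expressed genes. This
#' standardized variance removes the mean-variance trend so that biologically
#' variable genes rank above equally-expressed housekeeping genes. Ties are
#' broken by gene id so the selection is deterministic.
#'
#' @param matrix Normalized [expr_matrix()].
#' @param n Number of genes to select (default 2000). If `n` exceeds the gene
#'   count all genes are returned with a warning.
#' @param span Loess span for the mean-variance trend fit.
#' @return Character vector of selected gene ids, ranked by decreasing
#'   standardized variance.
#' @export
select_hvg <- function(matrix, n = 2000, span = 0.3) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "normalized") stop("select_hvg expects the normalized layer", call. = FALSE)
  v <- matrix$values
  nc <- ncol(v)
  mu <- Matrix::rowMeans(v)
  ex2 <- Matrix::rowMeans(v^2)
  vars <- (ex2 - mu^2) * nc / max(1, nc - 1)
  vars[vars < 0] <- 0
  std_var <- rep(0, length(mu))
  fit_ok <- mu > 0 & vars > 0
  if (sum(fit_ok) >= 10) {
    lmu <- log10(mu[fit_ok])
    lv <- log10(vars[fit_ok])
    expected <- tryCatch({
      fit <- stats::loess(lv ~ lmu, span = span, degree = 2,
                          control = stats::loess.control(surface = "direct"))
      10^stats::predict(fit, lmu)
    }, error = function(e) NULL)
    if (is.null(expected) || any(!is.finite(expected)) || any(expected <= 0)) {
      expected <- mu[fit_ok]  # Poisson-like fallback trend
    }
    std_var[fit_ok] <- vars[fit_ok] / expected
  } else {
    std_var[fit_ok] <- vars[fit_ok]
  }
  if (n > length(mu)) {
    warning("n = ", n, " exceeds the number of genes; returning all ",
            length(mu), " genes", call. = FALSE)
    n <- length(mu)
  }
  ord <- order(-std_var, matrix$gene_ids)
  matrix$gene_ids[ord[seq_len(n)]]
}

#' PCA embedding of cells on scaled highly variable genes
#'
#' Each selected gene is z-scored across cells, z-values are clipped at +/-10
#' to bound single-cell outlier leverage, and the cells are decomposed by PCA.
#' Component signs are fixed by making the largest-magnitude gene loading of
#' each component positive, so the embedding is fully deterministic.
#'
#' @param matrix Normalized [expr_matrix()].
#' @param genes Character vector of genes to use (typically from
#'   [select_hvg()]).
#' @param n_pcs Number of components (default 30); reduced with a warning if
#'   it reaches the rank limit `min(n_cells, n_genes) - 1`.
#' @param clip Absolute z-score clip value.
#' @return Numeric matrix, cells x components, with cell ids as row names and
#'   the component standard deviations in attribute `"sdev"`.
#' @export
embed_pca <- function(matrix, genes, n_pcs = 30, clip = 10) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "normalized") stop("embed_pca expects the normalized layer", call. = FALSE)
  miss <- setdiff(genes, matrix$gene_ids)
  if (length(miss)) stop("genes absent from matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  x <- t(as.matrix(matrix$values[match(genes, matrix$gene_ids), , drop = FALSE]))
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- Inf  # constant genes contribute nothing
  z <- sweep(sweep(x, 2, mu, `-`), 2, sdv, `/`)
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  limit <- min(nrow(z), ncol(z)) - 1L
  if (n_pcs > limit) {
    warning("n_pcs reduced from ", n_pcs, " to ", limit, call. = FALSE)
    n_pcs <- limit
  }
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  for (j in seq_len(n_pcs)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- matrix$cell_ids
  attr(scores, "sdev") <- pc$sdev[seq_len(n_pcs)]
  scores
}
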