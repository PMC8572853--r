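rank_and_ties <- function(X) {
  n_genes <- nrow(X)
  R <- matrix(0, n_genes, ncol(X))
  tie <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    x <- X[g, ]
    R[g, ] <- rank(x)
    len <- rle(sort(x))$lengths
    tie[g] <- sum(len^3 - len)
  }
  list(R = R, tie = tie)
}

# Wilcoxon rank-sum p-values for every row of a rank matrix against one group
# split. Uses the exact null distribution when a row has no ties and both
# groups have fewer than 50 observations (the classical switch), otherwise the
# tie-corrected normal approximation with continuity correction.
ranksum_engine <- function(ranks, tie, in_group) {
  N <- ncol(ranks)
  n1 <- sum(in_group)
  n2 <- N - n1
  W <- as.vector(ranks %*% in_group)
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie / (N * (N - 1)))
  z <- U - mu
  sigma <- sqrt(pmax(sigma2, 0))
  zc <- (z - sign(z) * 0.5) / ifelse(sigma > 0, sigma, Inf)
  p <- 2 * stats::pnorm(-abs(zc))
  p[sigma == 0] <- 1
  p <- pmin(p, 1)
  exact <- tie == 0 & n1 < 50 & n2 < 50
  if (any(exact)) {
    ue <- U[exact]
    upper <- ue > mu
    pe <- numeric(length(ue))
    if (any(upper)) pe[upper] <- 2 * stats::pwilcox(ue[upper] - 1, n1, n2,
                                                    lower.tail = FALSE)
    if (any(!upper)) pe[!upper] <- 2 * stats::pwilcox(ue[!upper], n1, n2)
    p[exact] <- pmin(pe, 1)
  }
  list(U = U, p = p)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' The scalar form of the marker test: exact null distribution when there are
#' no ties and both groups have fewer than 50 observations, tie-corrected
#' normal approximation with continuity correction otherwise.
#'
#' @param x,y Numeric vectors for the two groups.
#' @return List with `U` (Mann-Whitney statistic of `x`) and `p` (two-sided).
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  X <- matrix(c(x, y), nrow = 1)
  rt <- rank_and_ties(X)
  res <- ranksum_engine(rt$R, rt$tie, c(rep(TRUE, length(x)), rep(FALSE, length(y))))
  list(U = res$U[1], p = res$p[1])
}

#' Per-cluster marker detection by one-vs-rest Wilcoxon rank-sum
#'
#' For every gene and every cluster, tests the cluster's cells against all
#' other cells. The fold change is
#' `log2((m_in + 1) / (m_out + 1))` with `m` the group mean of `expm1`
#' (de-logged) normalized expression, and p-values are Benjamini-Hochberg
#' adjusted across genes within each cluster (each cluster's marker list is
#' its own family).
#'
#' @param matrix Normalized [expr_matrix()].
#' @param clusters Cluster assignment (see [cluster_labels()]).
#' @param min_cells Clusters below this size are skipped with a warning
#'   (default 3).
#' @return Data frame of marker records: `gene`, `cluster`, `log2_fc`,
#'   `p_value`, `p_adjusted`, `pct_in`, `pct_out`.
#' @export
rank_sum_markers <- function(matrix, clusters, min_cells = 3) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "normalized") {
    stop("rank_sum_markers expects the normalized layer", call. = FALSE)
  }
  labels <- cluster_labels(clusters)
  labels <- labels[matrix$cell_ids]
  if (anyNA(labels)) stop("every cell must carry a cluster label", call. = FALSE)
  lev <- unique(labels[order(nchar(labels), labels)])
  if (length(lev) < 2) stop("need at least two clusters", call. = FALSE)
  X <- as.matrix(matrix$values)
  rt <- rank_and_ties(X)
  E <- expm1(X)
  out <- vector("list", length(lev))
  for (i in seq_along(lev)) {
    cl <- lev[i]
    in_group <- labels == cl
    if (sum(in_group) < min_cells) {
      warning("cluster ", cl, " has fewer than ", min_cells,
              " cells; skipped", call. = FALSE)
      next
    }
    res <- ranksum_engine(rt$R, rt$tie, in_group)
    m_in <- rowMeans(E[, in_group, drop = FALSE])
    m_out <- rowMeans(E[, !in_group, drop = FALSE])
    out[[i]] <- data.frame(
      gene = matrix$gene_ids,
      cluster = cl,
      log2_fc = log2((m_in + 1) / (m_out + 1)),
      p_value = res$p,
      p_adjusted = bh_adjust(res$p),
      pct_in = rowMeans(X[, in_group, drop = FALSE] > 0),
      pct_out = rowMeans(X[, !in_group, drop = FALSE] > 0),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Controls the false discovery rate: sort p ascending,
#' `adj_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, returned in input
#' order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric", call. = FALSE)
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Filter marker records on significance and effect size
#'
#' Keeps records with adjusted p strictly below `alpha` AND absolute log2 fold
#' change strictly above `min_abs_log2fc` (boundary records are dropped).
#'
#' @param records Marker data frame from [rank_sum_markers()].
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param min_abs_log2fc Absolute log2 fold-change cutoff (default 2).
#' @return The filtered records.
#' @export
significant_markers <- function(records, alpha = 0.05, min_abs_log2fc = 2) {
  stopifnot(all(c("p_adjusted", "log2_fc") %in% names(records)))
  out <- records[records$p_adjusted < alpha & abs(records$log2_fc) > min_abs_log2fc, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}
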