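#' Read a ligand-receptor pair table
#'
#' @param path CSV with columns `ligand`, `receptor`.
#' @return Data frame of pairs.
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(df))) {
    stop("pair table must have columns 'ligand' and 'receptor'", call. = FALSE)
  }
  df[, c("ligand", "receptor")]
}

#' Bundled ligand-receptor pair fixture
#'
#' Signalling pairs central to the modelled inflammation system (macrophage
#' maintenance, chemoattraction, IL-1 regulation, IGF signalling) that are
#' also present in the default synthetic gene catalogue.
#'
#' @return Data frame with columns `ligand`, `receptor`.
#' @export
default_lr_pairs <- function() {
  path <- system.file("extdata", "lr_pairs.csv", package = "phagodual")
  if (nzchar(path) && file.exists(path)) return(read_lr_pairs(path))
  data.frame(
    ligand   = c("Csf1", "Il34", "Ccl3", "Cxcl1", "Il1b", "Igf1"),
    receptor = c("Csf1r", "Csf1r", "Ccr5", "Cxcr2", "Il1r2", "Igf1r"),
    stringsAsFactors = FALSE)
}

#' Mean normalized expression per cluster
#'
#' @param matrix Normalized [expr_matrix()].
#' @param clusters Cluster assignment (see [cluster_labels()]).
#' @return Numeric matrix, clusters x genes.
#' @export
cluster_means <- function(matrix, clusters) {
  stopifnot(inherits(matrix, "expr_matrix"))
  labels <- cluster_labels(clusters)
  labels <- labels[matrix$cell_ids]
  if (anyNA(labels)) stop("every cell must carry a cluster label", call. = FALSE)
  lev <- unique(labels[order(nchar(labels), labels)])
  sizes <- table(labels)[lev]
  if (any(sizes == 0)) stop("empty cluster present", call. = FALSE)
  ind <- outer(labels, lev, `==`) * 1
  means <- t(as.matrix(matrix$values %*% ind))
  means <- sweep(means, 1, as.numeric(sizes), `/`)
  dimnames(means) <- list(lev, matrix$gene_ids)
  means
}

#' Ligand-receptor interaction screen with a permutation null
#'
#' For every (ligand-receptor pair, sender cluster, receiver cluster)
#' combination (including sender = receiver) the interaction score is the
#' product of the sender's mean ligand expression and the receiver's mean
#' receptor expression. A record is valid only when both cluster means reach
#' the expression cutoff (default 0.2). For valid records, significance comes
#' from a label-permutation null: cluster labels are shuffled over cells
#' `n_perm` times, the score recomputed each time, and
#' `p = (1 + #permuted >= observed) / (n_perm + 1)` (add-one estimator, so
#' `p >= 1/(n_perm+1)` and never 0). Benjamini-Hochberg adjustment is applied
#' across valid records. Pairs whose genes are absent are skipped with a
#' message.
#'
#' @param matrix Normalized [expr_matrix()].
#' @param clusters Cluster assignment.
#' @param pairs Data frame with columns `ligand`, `receptor`.
#' @param cutoff Validity cutoff on cluster-mean normalized expression.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return Data frame of interaction records: `ligand`, `receptor`, `sender`,
#'   `receiver`, `mean_l`, `mean_r`, `score`, `valid`, `p_value`,
#'   `p_adjusted` (p fields are `NA` for invalid records).
#' @export
screen_interactions <- function(matrix, clusters, pairs, cutoff = 0.2,
                                n_perm = 1000, seed = 1L) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  present <- pairs$ligand %in% matrix$gene_ids & pairs$receptor %in% matrix$gene_ids
  if (any(!present)) {
    message(sum(!present), " pair(s) skipped (gene absent from matrix)")
  }
  pairs <- pairs[present, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no ligand-receptor pairs with both genes present", call. = FALSE)
  labels <- cluster_labels(clusters)[matrix$cell_ids]
  means <- cluster_means(matrix, clusters)
  lev <- rownames(means)
  grid <- expand.grid(pair = seq_len(nrow(pairs)), sender = lev, receiver = lev,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec <- data.frame(
    ligand = pairs$ligand[grid$pair],
    receptor = pairs$receptor[grid$pair],
    sender = grid$sender,
    receiver = grid$receiver,
    stringsAsFactors = FALSE)
  rec$mean_l <- means[cbind(rec$sender, rec$ligand)]
  rec$mean_r <- means[cbind(rec$receiver, rec$receptor)]
  rec$score <- rec$mean_l * rec$mean_r
  rec$valid <- rec$mean_l >= cutoff & rec$mean_r >= cutoff
  rec$p_value <- NA_real_
  rec$p_adjusted <- NA_real_
  vi <- which(rec$valid)
  if (length(vi)) {
    genes <- unique(c(rec$ligand[vi], rec$receptor[vi]))
    sub <- as.matrix(matrix$values[match(genes, matrix$gene_ids), , drop = FALSE])
    rownames(sub) <- genes
    sizes <- as.numeric(table(labels)[lev])
    obs <- rec$score[vi]
    li <- match(rec$ligand[vi], genes)
    ri <- match(rec$receptor[vi], genes)
    si <- match(rec$sender[vi], lev)
    rj <- match(rec$receiver[vi], lev)
    count <- integer(length(vi))
    withr::with_seed(seed, {
      for (b in seq_len(n_perm)) {
        perm <- sample(labels)
        ind <- outer(perm, lev, `==`) * 1
        pm <- sweep(t(sub %*% ind), 1, sizes, `/`)  # clusters x genes
        sc <- pm[cbind(si, li)] * pm[cbind(rj, ri)]
        count <- count + (sc >= obs)
      }
    })
    rec$p_value[vi] <- (1 + count) / (n_perm + 1)
    rec$p_adjusted[vi] <- bh_adjust(rec$p_value[vi])
  }
  attr(rec, "cutoff") <- cutoff
  attr(rec, "n_perm") <- n_perm
  attr(rec, "seed") <- seed
  rec
}

#' Count significant interactions per directed cluster pair
#'
#' @param records Output of [screen_interactions()].
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Integer matrix, sender x receiver, of counts of valid records with
#'   `p_adjusted < alpha`.
#' @export
interaction_counts <- function(records, alpha = 0.05) {
  lev <- unique(c(records$sender, records$receiver))
  lev <- lev[order(nchar(lev), lev)]
  m <- matrix(0L, length(lev), length(lev), dimnames = list(sender = lev, receiver = lev))
  sig <- records$valid & !is.na(records$p_adjusted) & records$p_adjusted < alpha
  if (any(sig)) {
    tab <- table(factor(records$sender[sig], lev), factor(records$receiver[sig], lev))
    m[] <- as.integer(tab)
  }
  m
}
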