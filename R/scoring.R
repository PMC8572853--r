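#' Partition genes into expression bins
#'
#' Genes are ranked by their mean normalized expression across all cells (ties
#' broken by gene id, ascending) and the rank order is split into `n_bins`
#' contiguous, near-equal groups. When the gene count is not divisible by
#' `n_bins` the remainder genes are given, one each, to the lowest bins, so
#' bin sizes differ by at most one. Bin 1 holds the lowest-expressed genes and
#' bin `n_bins` the highest.
#'
#' @param matrix Normalized [expr_matrix()].
#' @param n_bins Number of bins (default 25).
#' @return Object of class `bin_assignment`: list with `n_bins`, `bins`
#'   (named integer vector gene -> bin), `bin_genes` (list of gene vectors)
#'   and `means` (named mean expression).
#' @export
assign_bins <- function(matrix, n_bins = 25) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "normalized") stop("assign_bins expects the normalized layer", call. = FALSE)
  n_genes <- length(matrix$gene_ids)
  if (n_bins > n_genes) {
    stop("n_bins (", n_bins, ") exceeds the number of genes (", n_genes, ")",
         call. = FALSE)
  }
  means <- Matrix::rowMeans(matrix$values)
  names(means) <- matrix$gene_ids
  ord <- order(means, matrix$gene_ids)
  base <- n_genes %/% n_bins
  r <- n_genes %% n_bins
  sizes <- base + (seq_len(n_bins) <= r)
  bin_of_rank <- rep.int(seq_len(n_bins), sizes)
  bins <- integer(n_genes)
  bins[ord] <- bin_of_rank
  names(bins) <- matrix$gene_ids
  bin_genes <- split(matrix$gene_ids[ord], bin_of_rank)
  names(bin_genes) <- as.character(seq_len(n_bins))
  structure(list(n_bins = n_bins, bins = bins, bin_genes = bin_genes,
                 means = means),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat(sprintf("<bin_assignment> %d genes in %d bins (sizes %d-%d)\n",
              length(x$bins), x$n_bins, min(lengths(x$bin_genes)),
              max(lengths(x$bin_genes))))
  invisible(x)
}

#' Sample expression-matched control genes for a signature
#'
#' For each target gene, draws up to `n_ctrl` genes uniformly without
#' replacement from the target's expression bin, excluding every signature
#' gene (preventing self-matching inflation). The pooled control multiset is
#' the concatenation over targets, so a gene drawn for two targets counts
#' twice. Deterministic given the seed. Signature genes absent from the
#' matrix are dropped with a warning.
#'
#' @param bins A [assign_bins()] result.
#' @param signature A [gene_signature()].
#' @param n_ctrl Controls per target gene (default 100); when a bin has fewer
#'   eligible genes all of them are taken.
#' @param seed RNG seed.
#' @return Object of class `control_set`: list with `targets`, `controls`
#'   (per-target character vectors), `pooled` (multiset), `n_ctrl`, `seed`.
#' @export
sample_controls <- function(bins, signature, n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(bins, "bin_assignment"), inherits(signature, "gene_signature"))
  present <- signature$genes[signature$genes %in% names(bins$bins)]
  absent <- setdiff(signature$genes, present)
  if (length(absent)) {
    warning("signature '", signature$name, "': ", length(absent),
            " gene(s) absent from matrix: ",
            paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  if (length(present) == 0L) {
    stop("signature '", signature$name, "' has no genes present in the matrix",
         call. = FALSE)
  }
  controls <- withr::with_seed(seed, {
    lapply(present, function(g) {
      b <- bins$bins[[g]]
      pool <- setdiff(bins$bin_genes[[as.character(b)]], signature$genes)
      if (length(pool) == 0L) {
        stop("bin ", b, " contains no non-signature genes to control for '",
             g, "'", call. = FALSE)
      }
      if (length(pool) <= n_ctrl) pool else sample(pool, n_ctrl)
    })
  })
  names(controls) <- present
  structure(list(targets = present, controls = controls,
                 pooled = unlist(controls, use.names = FALSE),
                 n_ctrl = n_ctrl, seed = seed),
            class = "control_set")
}

#' Cell Score of one signature for every cell
#'
#' The Cell Score (CS) of a cell is the mean normalized expression of the
#' target gene set minus the mean over the pooled control multiset drawn from
#' the targets' expression bins:
#' `CS = mean(Gt) - mean(Gc)`. Because the controls are matched on mean
#' expression, a positive score reflects program activity above
#' expression-matched background rather than overall transcriptional output.
#'
#' @param matrix Normalized [expr_matrix()].
#' @param signature A [gene_signature()].
#' @param bins A [assign_bins()] result on the same matrix.
#' @param n_ctrl Controls per target gene (default 100).
#' @param seed RNG seed for the control draw.
#' @param control_set Optional precomputed [sample_controls()] result
#'   (overrides `n_ctrl`/`seed`).
#' @return Named numeric vector of scores, one per cell.
#' @export
score_cells <- function(matrix, signature, bins, n_ctrl = 100, seed = 1L,
                        control_set = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "normalized") stop("score_cells expects the normalized layer", call. = FALSE)
  if (is.null(control_set)) {
    control_set <- sample_controls(bins, signature, n_ctrl = n_ctrl, seed = seed)
  }
  v <- matrix$values
  t_idx <- match(control_set$targets, matrix$gene_ids)
  t_mean <- Matrix::colMeans(v[t_idx, , drop = FALSE])
  w <- table(control_set$pooled)
  c_idx <- match(names(w), matrix$gene_ids)
  wts <- as.numeric(w)
  c_mean <- as.vector(wts %*% v[c_idx, , drop = FALSE]) / sum(wts)
  stats::setNames(as.numeric(t_mean - c_mean), matrix$cell_ids)
}

#' Cell Scores for a list of signatures
#'
#' Each signature gets an independent control draw from a per-signature
#' substream of the seed, so scoring signatures together or alone yields
#' identical columns.
#'
#' @param matrix Normalized [expr_matrix()].
#' @param signatures List of [gene_signature()] objects with unique names.
#' @param bins A [assign_bins()] result.
#' @param n_ctrl Controls per target gene.
#' @param seed Base RNG seed.
#' @return Data frame `cell_id` plus one numeric column per signature, with
#'   attributes `seed`, `n_bins`, `n_ctrl`, `layer`.
#' @export
score_many <- function(matrix, signatures, bins, n_ctrl = 100, seed = 1L) {
  nms <- vapply(signatures, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate signature names", call. = FALSE)
  cols <- lapply(signatures, function(s) {
    score_cells(matrix, s, bins, n_ctrl = n_ctrl,
                seed = substream_seed(seed, s$name))
  })
  out <- data.frame(cell_id = matrix$cell_ids, stringsAsFactors = FALSE)
  for (i in seq_along(cols)) out[[nms[i]]] <- unname(cols[[i]])
  attr(out, "seed") <- seed
  attr(out, "n_bins") <- bins$n_bins
  attr(out, "n_ctrl") <- n_ctrl
  attr(out, "layer") <- matrix$layer
  out
}
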