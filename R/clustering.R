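knn_edges <- function(pc, k) {
  n <- nrow(pc)
  block <- 512L
  sq <- rowSums(pc^2)
  from <- integer(0)
  to <- integer(0)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    d2 <- outer(sq[idx], sq, `+`) - 2 * pc[idx, , drop = FALSE] %*% t(pc)
    for (r in seq_along(idx)) {
      d2[r, idx[r]] <- Inf
      nb <- order(d2[r, ])[seq_len(k)]
      from <- c(from, rep.int(idx[r], k))
      to <- c(to, nb)
    }
  }
  cbind(from, to)
}

#' Graph-based clustering of cells in PC space
#'
#' Builds a k-nearest-neighbour graph (Euclidean distance between PC
#' coordinates), then applies Louvain modularity optimization with the given
#' resolution. Labels are `C0, C1, ...` ordered by decreasing cluster size and
#' the run is deterministic given the seed.
#'
#' @param pc_coords Cells x components matrix with cell ids as row names.
#' @param resolution Modularity resolution (default 0.6).
#' @param k_neighbors Neighbours per cell (default 20; reduced with a warning
#'   when fewer cells are available).
#' @param seed RNG seed for the community detection.
#' @return Object of class `cluster_assignment`: a list with `assignment`
#'   (data frame `cell_id`, `cluster`), `resolution`, `k_neighbors`, `seed`.
#' @export
cluster_cells <- function(pc_coords, resolution = 0.6, k_neighbors = 20, seed = 1L) {
  stopifnot(is.matrix(pc_coords), !is.null(rownames(pc_coords)))
  n <- nrow(pc_coords)
  if (n < 2) stop("need at least two cells to cluster", call. = FALSE)
  if (k_neighbors >= n) {
    warning("k_neighbors reduced from ", k_neighbors, " to ", n - 1L, call. = FALSE)
    k_neighbors <- n - 1L
  }
  edges <- knn_edges(pc_coords, k_neighbors)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- withr::with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(paste0("C", seq_along(sizes) - 1L), names(sizes))
  assignment <- data.frame(cell_id = rownames(pc_coords),
                           cluster = unname(relabel[as.character(memb)]),
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment, resolution = resolution,
                 k_neighbors = k_neighbors, seed = seed),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d cells, %d clusters (resolution %.2f)\n",
              nrow(x$assignment), length(unique(x$assignment$cluster)),
              x$resolution))
  invisible(x)
}

#' Cluster labels as a named vector
#'
#' @param clusters A `cluster_assignment` (or a data frame with `cell_id`,
#'   `cluster`, or an already-named vector).
#' @return Named character vector, cell id -> cluster label.
#' @export
cluster_labels <- function(clusters) {
  if (inherits(clusters, "cluster_assignment")) clusters <- clusters$assignment
  if (is.data.frame(clusters)) {
    stats::setNames(as.character(clusters$cluster), clusters$cell_id)
  } else {
    stopifnot(!is.null(names(clusters)))
    stats::setNames(as.character(clusters), names(clusters))
  }
}
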