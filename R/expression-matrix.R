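#' Construct an expression matrix object
#'
#' The container shared by every stage of the pipeline: a sparse gene x cell
#' matrix tagged with its layer. The `raw` layer holds non-negative integer
#' counts; the `normalized` layer holds log total-count-normalized values.
#' When a matrix is normalized the raw counts are retained alongside in the
#' `raw` field.
#'
#' @param values Gene x cell matrix (dense or sparse); coerced to `dgCMatrix`.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param cell_ids Character vector of unique cell identifiers (columns).
#' @param layer `"raw"` or `"normalized"`.
#' @param raw Optional raw-count `dgCMatrix` carried alongside a normalized
#'   layer.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, gene_ids, cell_ids, layer = c("raw", "normalized"),
                        raw = NULL) {
  layer <- match.arg(layer)
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE), "generalMatrix"),
                        "CsparseMatrix")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids are not allowed", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids are not allowed", call. = FALSE)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(cell_ids)) {
    stop("matrix dimensions (", nrow(values), " x ", ncol(values),
         ") do not match gene/cell id lengths (", length(gene_ids), " x ",
         length(cell_ids), ")", call. = FALSE)
  }
  if (length(values@x) && any(values@x < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  if (layer == "raw" && length(values@x) && any(values@x != round(values@x))) {
    stop("raw layer must contain integer counts", call. = FALSE)
  }
  dimnames(values) <- list(as.character(gene_ids), as.character(cell_ids))
  structure(list(values = values,
                 gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids),
                 layer = layer,
                 raw = raw),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, layer = %s, %d nonzeros\n",
              nrow(x$values), ncol(x$values), x$layer, length(x$values@x)))
  invisible(x)
}

#' Subset an expression matrix by genes and/or cells
#'
#' @param em An `expr_matrix`.
#' @param genes,cells Character identifiers (or logical/integer indices) to
#'   keep; `NULL` keeps all.
#' @return A new `expr_matrix` on the same layer (the raw companion layer, if
#'   present, is subset consistently).
#' @export
em_subset <- function(em, genes = NULL, cells = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  gi <- if (is.null(genes)) seq_along(em$gene_ids) else genes
  ci <- if (is.null(cells)) seq_along(em$cell_ids) else cells
  if (is.character(gi)) {
    miss <- setdiff(gi, em$gene_ids)
    if (length(miss)) stop("unknown gene ids: ", paste(utils::head(miss, 5), collapse = ", "),
                           call. = FALSE)
    gi <- match(gi, em$gene_ids)
  }
  if (is.character(ci)) {
    miss <- setdiff(ci, em$cell_ids)
    if (length(miss)) stop("unknown cell ids: ", paste(utils::head(miss, 5), collapse = ", "),
                           call. = FALSE)
    ci <- match(ci, em$cell_ids)
  }
  raw <- if (!is.null(em$raw)) em$raw[gi, ci, drop = FALSE] else NULL
  expr_matrix(em$values[gi, ci, drop = FALSE], em$gene_ids[gi], em$cell_ids[ci],
              layer = em$layer, raw = raw)
}

read_id_file <- function(path, what) {
  if (!file.exists(path)) stop(what, " file '", path, "' does not exist", call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  # features.tsv may carry (id, symbol, type); use the symbol column when present
  if (what == "features" && all(ncols >= 2L)) {
    vapply(fields, `[[`, character(1), 2L)
  } else {
    vapply(fields, `[[`, character(1), 1L)
  }
}

#' Read a Matrix Market sparse count matrix with feature and barcode files
#'
#' Genes are rows and cells are columns (1-based coordinate MTX). Gene and
#' cell order is preserved exactly as given in the feature/barcode files.
#'
#' @param mtx_path Path to the `.mtx` file.
#' @param features_path Path to the features TSV (one gene per line; if the
#'   file has two or more tab-separated columns the second, the gene symbol,
#'   is used).
#' @param barcodes_path Path to the barcodes TSV (one cell per line).
#' @return An `expr_matrix` with `layer = "raw"`.
#' @export
read_matrix <- function(mtx_path, features_path, barcodes_path) {
  if (!file.exists(mtx_path)) stop("matrix file '", mtx_path, "' does not exist", call. = FALSE)
  m <- tryCatch(Matrix::readMM(mtx_path), error = function(e) {
    stop("'", mtx_path, "' is not a valid Matrix Market file: ", conditionMessage(e),
         call. = FALSE)
  })
  genes <- read_id_file(features_path, "features")
  cells <- read_id_file(barcodes_path, "barcodes")
  if (nrow(m) != length(genes)) {
    stop("dimension mismatch: '", mtx_path, "' declares ", nrow(m),
         " rows but '", features_path, "' has ", length(genes), " features",
         call. = FALSE)
  }
  if (ncol(m) != length(cells)) {
    stop("dimension mismatch: '", mtx_path, "' declares ", ncol(m),
         " columns but '", barcodes_path, "' has ", length(cells), " barcodes",
         call. = FALSE)
  }
  expr_matrix(m, genes, cells, layer = "raw")
}

#' Write an expression matrix as an MTX trio
#'
#' Inverse of [read_matrix()]: round-trips gene/cell ordering and values
#' losslessly (raw counts exactly; normalized values to printed precision).
#'
#' @param em An `expr_matrix`.
#' @param dir Output directory (created if absent).
#' @param prefix Optional filename prefix.
#' @return Invisibly, the three paths written.
#' @export
write_matrix <- function(em, dir, prefix = "") {
  stopifnot(inherits(em, "expr_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("matrix.mtx", "features.tsv", "barcodes.tsv")))
  Matrix::writeMM(em$values, paths[1])
  writeLines(em$gene_ids, paths[2])
  writeLines(em$cell_ids, paths[3])
  invisible(paths)
}
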