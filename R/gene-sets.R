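#' Construct a gene signature
#'
#' A named, non-empty gene set; duplicate genes are removed preserving first
#' occurrence.
#'
#' @param name Signature name.
#' @param genes Character vector of gene identifiers (case-sensitive symbols).
#' @return Object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) {
    stop("gene set '", name, "' has an empty gene list", call. = FALSE)
  }
  structure(list(name = name, genes = unique(genes)), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes (%s%s)\n", x$name, length(x$genes),
              paste(utils::head(x$genes, 4), collapse = ", "),
              if (length(x$genes) > 4) ", ..." else ""))
  invisible(x)
}

#' Read gene signatures from a tab-separated gene-set file
#'
#' Each record is one line: the set name followed by its genes, tab-separated.
#' With `description = TRUE` the second field is treated as a free-text
#' description (the strict GMT layout) and skipped.
#'
#' @param path File path.
#' @param description Does each record carry a description field after the
#'   name? Default `FALSE`.
#' @return List of [gene_signature()] objects, in file order.
#' @export
read_gene_sets <- function(path, description = FALSE) {
  if (!file.exists(path)) stop("gene-set file '", path, "' does not exist", call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("gene-set file '", path, "' contains no records", call. = FALSE)
    return(list())
  }
  skip <- if (description) 2L else 1L
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) <= skip) {
      stop("gene set '", f[1], "' has an empty gene list", call. = FALSE)
    }
    gene_signature(f[1], f[-seq_len(skip)])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene signatures to a tab-separated gene-set file
#'
#' @param sets List of [gene_signature()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) paste(c(s$name, s$genes), collapse = "\t"),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-cell table (CSV with provenance header)
#'
#' @param table Data frame with one row per cell.
#' @param path Output path.
#' @param seed,config_hash Optional provenance recorded as comment lines.
#' @return Invisibly, `path`.
#' @export
write_cell_table <- function(table, path, seed = NULL, config_hash = NULL) {
  write_annotated_csv(table, path, seed = seed, config_hash = config_hash)
}

#' Write a cell-score table (CSV with provenance header)
#'
#' @inheritParams write_cell_table
#' @param score_table Data frame of per-cell signature scores.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(score_table, path, seed = NULL, config_hash = NULL) {
  write_annotated_csv(score_table, path, seed = seed, config_hash = config_hash)
}
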