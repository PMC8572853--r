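# Shared fixtures built in code: small generator configurations and a tiny
# deterministic normalized matrix for scoring arithmetic.

small_config <- function(n_normal = 200, n_inflamed = 250, n_genes = 800,
                         seed = 1L) {
  default_study_config(n_genes = n_genes,
                       n_cells = c(normal = n_normal, inflamed = n_inflamed),
                       seed = seed)
}

null_config <- function(n_normal = 500, n_inflamed = 500, n_genes = 2000,
                        seed = 1L) {
  cfg <- default_study_config(n_genes = n_genes,
                              n_cells = c(normal = n_normal, inflamed = n_inflamed),
                              seed = seed)
  cfg$program_log2fc <- 0
  cfg$phago_log2fc <- 0
  cfg$dual_specs <- lapply(cfg$dual_specs, function(d) { d$log2fc <- 0; d })
  cfg$doublet_rate <- 0
  cfg
}

toy_norm_matrix <- function(n_genes = 120, n_cells = 15, seed = 42) {
  withr::with_seed(seed, {
    v <- matrix(stats::rexp(n_genes * n_cells), n_genes, n_cells)
  })
  expr_matrix(v, sprintf("g%03d", seq_len(n_genes)),
              sprintf("c%03d", seq_len(n_cells)), layer = "normalized")
}

# QC -> normalize across both conditions, preserving original cell order
qc_and_normalize <- function(ds) {
  kept <- lapply(c("normal", "inflamed"), function(cond) {
    i <- which(ds$cells$condition == cond)
    filter_cells(em_subset(ds$matrix, cells = i), ds$cells[i, ], qc_preset(cond))
  })
  ids <- unlist(lapply(kept, function(k) k$cells$cell_id))
  ids <- ds$cells$cell_id[ds$cells$cell_id %in% ids]
  cells <- do.call(rbind, lapply(kept, `[[`, "cells"))
  cells <- cells[match(ids, cells$cell_id), ]
  rownames(cells) <- NULL
  list(matrix = normalize_total(em_subset(ds$matrix, cells = ids)),
       cells = cells)
}
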