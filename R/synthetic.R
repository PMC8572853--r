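#' Validate a synthetic-data generator configuration
#'
#' A generator configuration describes a two-condition (normal vs inflamed)
#' scRNA-seq experiment: a gene catalogue partitioned into marker programs, a
#' cell-type catalogue with per-condition composition, planted dual-feature
#' populations, doublets, mitochondrial content and a negative-binomial count
#' law with log-normal library sizes.
#'
#' @param config A generator configuration list (see [default_study_config()]
#'   for the field set).
#' @return The validated config, invisibly.
#' @export
validate_generator_config <- function(config) {
  req <- c("n_genes", "n_cells", "gene_ids", "programs", "cell_types",
           "type_programs", "composition", "program_log2fc", "phago_log2fc",
           "dual_specs", "dispersion", "lib_meanlog", "lib_sdlog",
           "mito_genes", "mito_fraction", "doublet_rate",
           "doublet_depth_factor", "baseline_sdlog", "seed")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("generator config is missing fields: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  with(config, {
    stopifnot(n_genes >= 1, length(gene_ids) == n_genes, !anyDuplicated(gene_ids))
    if (!all(c("normal", "inflamed") %in% names(n_cells))) {
      stop("n_cells must be named with conditions 'normal' and 'inflamed'", call. = FALSE)
    }
    for (p in names(programs)) {
      idx <- programs[[p]]
      if (any(idx < 1 | idx > n_genes)) {
        stop("program '", p, "' has gene indices out of range 1..", n_genes, call. = FALSE)
      }
    }
    all_idx <- unlist(programs, use.names = FALSE)
    if (anyDuplicated(all_idx)) stop("marker programs must be disjoint", call. = FALSE)
    if (!setequal(rownames(composition), cell_types)) {
      stop("composition rows must match the cell-type catalogue", call. = FALSE)
    }
    for (cond in c("normal", "inflamed")) {
      s <- sum(composition[, cond])
      if (abs(s - 1) > 1e-8) {
        stop("composition for condition '", cond, "' sums to ", format(s),
             ", not 1", call. = FALSE)
      }
    }
    bad <- setdiff(unlist(type_programs), names(programs))
    if (length(bad)) stop("unknown programs in type_programs: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (spec in dual_specs) {
      stopifnot(spec$fraction >= 0, spec$fraction <= 1, spec$log2fc >= 0)
      if (!spec$host_type %in% cell_types) {
        stop("dual spec '", spec$name, "' host type '", spec$host_type,
             "' is not in the cell-type catalogue", call. = FALSE)
      }
      if (!all(spec$programs %in% names(programs))) {
        stop("dual spec '", spec$name, "' references unknown programs", call. = FALSE)
      }
    }
    stopifnot(program_log2fc >= 0, phago_log2fc >= 0, dispersion >= 0,
              lib_sdlog >= 0, mito_fraction >= 0, mito_fraction < 1,
              doublet_rate >= 0, doublet_rate < 1, doublet_depth_factor > 0)
  })
  invisible(config)
}

canonical_markers <- function() {
  list(
    neutrophil    = c("S100a8", "S100a9", "Mpo", "Ltf", "Camp", "Cxcr2", "Il1r2"),
    macrophage    = c("Adgre1", "Csf1r", "Itgam", "Lyz2", "Ccl3", "Cxcl1", "Il1b"),
    fibroblast    = c("Col1a1", "Sfrp4", "Pdgfra", "Dcn", "Il34", "Igf1r"),
    epithelial    = c("Epcam", "Krt18", "Krt8", "Cldn3", "Csf1"),
    t_cell        = c("Cd3e", "Cd3d", "Cd3g", "Ccr5"),
    dendritic     = c("Itgax", "Cd83", "Flt3"),
    endothelial   = c("Pecam1", "Cdh5", "Vwf"),
    b_cell        = c("Cd79a", "Cd79b", "Ms4a1"),
    phagocytosis  = c("Cd68", "Cd14", "Mertk", "Axl", "Msr1"),
    proliferation = c("Mki67", "Ccna2", "Ccnb1", "Cdk1", "Aspm", "Top2a"),
    osteoblastic  = c("Bmp5", "Cdh11", "Col5a2", "Col12a1", "Mmp2", "Sparc"),
    M1            = c("Nos2", "Tnf", "Cd86", "Il12b"),
    M2            = c("Mrc1", "Cd163", "Arg1", "Igf1", "Ccl22", "Retnla")
  )
}

#' Default study generator configuration
#'
#' Eight cell types whose per-condition composition mirrors the modelled tissue:
#' the normal middle-ear mucosa is dominated by epithelial cells and
#' fibroblasts (combined fraction about two-thirds), while the inflamed mucosa
#' is dominated by infiltrating neutrophils and macrophages. Three
#' dual-feature populations are planted, each co-elevating a lineage program
#' with the phagocytosis program: proliferation x phagocytosis, epithelial x
#' phagocytosis, and osteoblastic-stromal x phagocytosis. Professional
#' phagocytes (neutrophils, macrophages, dendritic cells) carry a milder
#' phagocytosis elevation; macrophages are polarized towards M2.
#'
#' @param n_genes Total genes in the catalogue (default 2000).
#' @param n_cells Named vector of cells per condition,
#'   `c(normal = 900, inflamed = 1200)`.
#' @param seed Default RNG seed recorded in the config.
#' @return A validated generator configuration list.
#' @export
default_study_config <- function(n_genes = 2000,
                                 n_cells = c(normal = 900, inflamed = 1200),
                                 seed = 1L) {
  program_sizes <- c(neutrophil = 50, macrophage = 50, fibroblast = 50,
                     epithelial = 50, t_cell = 50, dendritic = 50,
                     endothelial = 50, b_cell = 50,
                     phagocytosis = 40, proliferation = 40, osteoblastic = 40,
                     M1 = 30, M2 = 30)
  n_mito <- 10
  stopifnot(n_genes >= sum(program_sizes) + n_mito)
  gene_ids <- sprintf("Gene%04d", seq_len(n_genes))
  programs <- list()
  offset <- 0L
  marks <- canonical_markers()
  for (p in names(program_sizes)) {
    idx <- offset + seq_len(program_sizes[[p]])
    programs[[p]] <- idx
    nm <- marks[[p]]
    lbl <- c(nm, sprintf("%s.%02d", p, seq_len(length(idx) - length(nm))))
    gene_ids[idx] <- lbl
    offset <- offset + program_sizes[[p]]
  }
  mito_genes <- (n_genes - n_mito + 1L):n_genes
  gene_ids[mito_genes] <- c("Mt-nd1", "Mt-nd2", "Mt-co1", "Mt-co2", "Mt-atp6",
                            "Mt-cytb", "Mt-nd4", "Mt-nd5", "Mt-co3", "Mt-rnr1")
  cell_types <- c("neutrophil", "macrophage", "fibroblast", "epithelial",
                  "t_cell", "dendritic", "endothelial", "b_cell")
  composition <- cbind(
    normal   = c(neutrophil = 0.05, macrophage = 0.05, fibroblast = 0.28,
                 epithelial = 0.38, t_cell = 0.06, dendritic = 0.04,
                 endothelial = 0.10, b_cell = 0.04),
    inflamed = c(neutrophil = 0.40, macrophage = 0.22, fibroblast = 0.08,
                 epithelial = 0.12, t_cell = 0.07, dendritic = 0.04,
                 endothelial = 0.04, b_cell = 0.03))
  type_programs <- list(
    neutrophil = c("neutrophil", "phagocytosis"),
    macrophage = c("macrophage", "phagocytosis", "M2"),
    fibroblast = "fibroblast",
    epithelial = "epithelial",
    t_cell = "t_cell",
    dendritic = c("dendritic", "phagocytosis"),
    endothelial = "endothelial",
    b_cell = "b_cell")
  dual_specs <- list(
    list(name = "prolif_phago", host_type = "epithelial",
         lineage_program = "proliferation",
         programs = c("proliferation", "phagocytosis"),
         fraction = 0.05, log2fc = 2),
    list(name = "epi_phago", host_type = "epithelial",
         lineage_program = "epithelial",
         programs = c("epithelial", "phagocytosis"),
         fraction = 0.05, log2fc = 2),
    list(name = "osteo_phago", host_type = "fibroblast",
         lineage_program = "osteoblastic",
         programs = c("osteoblastic", "phagocytosis"),
         fraction = 0.05, log2fc = 2))
  config <- list(
    n_genes = n_genes,
    n_cells = n_cells,
    gene_ids = gene_ids,
    programs = programs,
    cell_types = cell_types,
    type_programs = type_programs,
    composition = composition,
    program_log2fc = 2,
    phago_log2fc = 1,
    dual_specs = dual_specs,
    dispersion = 0.3,
    lib_meanlog = log(2500),
    lib_sdlog = 0.35,
    mito_genes = mito_genes,
    mito_fraction = 0.05,
    doublet_rate = 0.05,
    doublet_depth_factor = 1.6,
    baseline_sdlog = 1.2,
    seed = as.integer(seed))
  validate_generator_config(config)
  config
}

type_profile <- function(config, type, baseline) {
  mult <- rep(1, config$n_genes)
  for (p in config$type_programs[[type]]) {
    lfc <- if (p == "phagocytosis") config$phago_log2fc else config$program_log2fc
    mult[config$programs[[p]]] <- mult[config$programs[[p]]] * 2^lfc
  }
  prof <- baseline * mult
  prof / sum(prof)
}

dual_profile <- function(config, type, spec, baseline) {
  mult <- rep(1, config$n_genes)
  for (p in config$type_programs[[type]]) {
    lfc <- if (p == "phagocytosis") config$phago_log2fc else config$program_log2fc
    mult[config$programs[[p]]] <- mult[config$programs[[p]]] * 2^lfc
  }
  # dual programs are raised to at least the dual effect (max rule, so a
  # program already active in the host lineage is not double-counted)
  for (p in spec$programs) {
    idx <- config$programs[[p]]
    mult[idx] <- pmax(mult[idx], 2^spec$log2fc)
  }
  prof <- baseline * mult
  prof / sum(prof)
}

#' Generate a synthetic two-condition scRNA-seq dataset with planted truth
#'
#' Counts are negative-binomially sampled (gamma-Poisson, gene-shared
#' dispersion) around `baseline x program multiplier x library size`, with
#' per-type profiles normalized so that the expected total counts per cell do
#' not depend on cell type. Dual-feature cells elevate both of their programs
#' multiplicatively; doublets are formed by summing two random parent cells'
#' counts and binomially thinning them to a (deeper-than-average) single-cell
#' library size. Fully deterministic given the seed.
#'
#' @param config Generator configuration (see [default_study_config()]).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list with elements `matrix` (raw [expr_matrix()]), `cells`
#'   (per-cell table with sample, condition and QC fields) and `truth` (list
#'   of `cells` and `genes` ground-truth tables).
#' @export
generate_dataset <- function(config, seed = config$seed) {
  validate_generator_config(config)
  withr::local_seed(seed)
  n_genes <- config$n_genes
  baseline <- stats::rlnorm(n_genes, meanlog = 0, sdlog = config$baseline_sdlog)
  # mitochondrial block gets a dedicated mean chosen to hit the expected
  # mitochondrial fraction of total counts
  mito <- config$mito_genes
  baseline[mito] <- config$mito_fraction / (1 - config$mito_fraction) *
    sum(baseline[-mito]) / length(mito)

  profiles <- lapply(config$cell_types, function(t) type_profile(config, t, baseline))
  names(profiles) <- config$cell_types

  cond_out <- lapply(c("normal", "inflamed"), function(cond) {
    n <- config$n_cells[[cond]]
    types <- sample(config$cell_types, n, replace = TRUE,
                    prob = config$composition[config$cell_types, cond])
    dual_of <- rep(NA_character_, n)
    for (spec in config$dual_specs) {
      host <- which(types == spec$host_type & is.na(dual_of))
      k <- floor(spec$fraction * sum(types == spec$host_type))
      if (k > 0 && length(host) >= k) {
        dual_of[sample(host, k)] <- spec$name
      }
    }
    lib <- stats::rlnorm(n, config$lib_meanlog, config$lib_sdlog)
    prof_mat <- matrix(0, n_genes, n)
    for (i in seq_len(n)) {
      prof_mat[, i] <- if (is.na(dual_of[i])) {
        profiles[[types[i]]]
      } else {
        spec <- config$dual_specs[[match(dual_of[i],
                 vapply(config$dual_specs, `[[`, character(1), "name"))]]
        dual_profile(config, types[i], spec, baseline)
      }
    }
    mu <- sweep(prof_mat, 2, lib, `*`)
    counts <- if (config$dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
             n_genes, n)
    } else {
      matrix(stats::rpois(length(mu), lambda = mu), n_genes, n)
    }
    doublet <- rep(FALSE, n)
    parents <- rep(NA_character_, n)
    n_d <- floor(config$doublet_rate * n)
    if (n_d > 0) {
      slots <- sample(n, n_d)
      doublet[slots] <- TRUE
      singles <- setdiff(seq_len(n), slots)
      for (s in slots) {
        pr <- sample(singles, 2)
        summed <- counts[, pr[1]] + counts[, pr[2]]
        target <- stats::rlnorm(1, config$lib_meanlog, config$lib_sdlog) *
          config$doublet_depth_factor
        p_keep <- min(1, target / max(1, sum(summed)))
        counts[, s] <- stats::rbinom(n_genes, summed, p_keep)
        parents[s] <- paste(types[pr[1]], types[pr[2]], sep = "+")
      }
      dual_of[slots] <- NA_character_
    }
    list(types = types, dual_of = dual_of, doublet = doublet, parents = parents,
         counts = counts,
         sample_id = paste0(cond, "_s", sample(3, n, replace = TRUE)),
         condition = rep(cond, n))
  })

  counts <- cbind(cond_out[[1]]$counts, cond_out[[2]]$counts)
  condition <- c(cond_out[[1]]$condition, cond_out[[2]]$condition)
  cell_ids <- paste0(condition, "_", sprintf("%04d", c(
    seq_len(config$n_cells[["normal"]]), seq_len(config$n_cells[["inflamed"]]))))
  types <- c(cond_out[[1]]$types, cond_out[[2]]$types)
  dual_of <- c(cond_out[[1]]$dual_of, cond_out[[2]]$dual_of)
  doublet <- c(cond_out[[1]]$doublet, cond_out[[2]]$doublet)
  parents <- c(cond_out[[1]]$parents, cond_out[[2]]$parents)
  sample_id <- c(cond_out[[1]]$sample_id, cond_out[[2]]$sample_id)

  em <- expr_matrix(counts, config$gene_ids, cell_ids, layer = "raw")
  cells <- compute_cell_qc(em)
  cells$sample_id <- sample_id
  cells$condition <- condition

  spec_prog <- vapply(config$dual_specs, function(s) paste(s$programs, collapse = "|"),
                      character(1))
  names(spec_prog) <- vapply(config$dual_specs, `[[`, character(1), "name")
  truth_cells <- data.frame(
    cell_id = cell_ids,
    truth_type = ifelse(doublet, "doublet", types),
    host_type = types,
    dual = !is.na(dual_of),
    dual_spec = dual_of,
    dual_programs = ifelse(is.na(dual_of), NA_character_, spec_prog[dual_of]),
    doublet = doublet,
    parent_types = parents,
    stringsAsFactors = FALSE)
  gene_program <- rep(NA_character_, n_genes)
  for (p in names(config$programs)) gene_program[config$programs[[p]]] <- p
  truth_genes <- data.frame(
    gene_id = config$gene_ids,
    program = gene_program,
    mito = seq_len(n_genes) %in% mito,
    stringsAsFactors = FALSE)

  list(matrix = em, cells = cells,
       truth = list(cells = truth_cells, genes = truth_genes))
}

#' Gene signatures for each marker program of a generator configuration
#'
#' @param config Generator configuration.
#' @param programs Optional character vector of program names (default: all).
#' @return Named list of [gene_signature()] objects.
#' @export
program_signatures <- function(config, programs = names(config$programs)) {
  sets <- lapply(programs, function(p) {
    gene_signature(p, config$gene_ids[config$programs[[p]]])
  })
  names(sets) <- programs
  sets
}
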