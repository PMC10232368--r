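#' Write a count matrix to disk
#'
#' `mtx_dir` writes the CellRanger-style triplet — `matrix.mtx`
#' (MatrixMarket coordinate, genes x cells, 1-based per the format),
#' `features.tsv`, `barcodes.tsv` — plus `cell_meta.tsv`. `csv` writes a
#' dense `counts.csv` (cells x genes) plus `cell_meta.csv`.
#'
#' @param cm A `count_matrix`.
#' @param path Output directory (created if needed).
#' @param format `"mtx_dir"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, format = c("mtx_dir", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx_dir") {
    m <- Matrix::Matrix(t(cm$counts), sparse = TRUE)   # genes x cells
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(colnames(cm$counts), file.path(path, "features.tsv"))
    writeLines(rownames(cm$counts), file.path(path, "barcodes.tsv"))
    utils::write.table(cm$cell_meta, file.path(path, "cell_meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(cm$counts), file.path(path, "counts.csv"))
    utils::write.csv(cm$cell_meta, file.path(path, "cell_meta.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#'
#' @param path Directory holding the files.
#' @param format `"mtx_dir"` or `"csv"`.
#' @return A `count_matrix`; integer data round-trips bit-exactly.
#' @export
read_counts <- function(path, format = c("mtx_dir", "csv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    m <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
    features <- readLines(file.path(path, "features.tsv"))
    barcodes <- readLines(file.path(path, "barcodes.tsv"))
    if (length(features) != nrow(m)) {
      abort("features.tsv length does not match the matrix gene dimension")
    }
    if (length(barcodes) != ncol(m)) {
      abort("barcodes.tsv length does not match the matrix cell dimension")
    }
    counts <- t(m)
    if (all(counts == round(counts))) storage.mode(counts) <- "integer"
    dimnames(counts) <- list(barcodes, features)
    meta_path <- file.path(path, "cell_meta.tsv")
    meta <- if (file.exists(meta_path)) {
      as_tibble(utils::read.table(meta_path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE))
    } else NULL
  } else {
    counts <- as.matrix(utils::read.csv(file.path(path, "counts.csv"),
                                        row.names = 1, check.names = FALSE))
    meta_path <- file.path(path, "cell_meta.csv")
    meta <- if (file.exists(meta_path)) {
      as_tibble(utils::read.csv(meta_path, stringsAsFactors = FALSE))
    } else NULL
  }
  count_matrix(counts, meta)
}

#' Read a one-to-one ortholog table
#'
#' @param path Two-column TSV (symbol_a, symbol_b), with or without header.
#' @return An [ortholog_map()]; non-injective tables are rejected.
#' @export
read_orthologs <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- identical(tolower(first[1:2]), c("symbol_a", "symbol_b"))
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 2) abort("ortholog table must have exactly two columns")
  names(tab) <- c("symbol_a", "symbol_b")
  ortholog_map(tab)
}

#' Write an ortholog map
#' @param map An `ortholog_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_orthologs <- function(map, path) {
  utils::write.table(map$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a factor model
#'
#' Stores gene and cell scores as TSVs plus a JSON header with the
#' hyperparameters and ELBO trace; the round trip preserves scores to the
#' stored precision (full double precision).
#'
#' @param model A `factor_model`.
#' @param path Output directory.
#' @return `path` (write) or the restored `factor_model` (read).
#' @export
write_factor_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(format(model$gene_scores, digits = 17, trim = TRUE),
                     file.path(path, "gene_scores.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(format(model$cell_scores, digits = 17, trim = TRUE),
                     file.path(path, "cell_scores.tsv"),
                     sep = "\t", quote = FALSE)
  header <- list(
    hyper = unclass(model$hyper), elbo_trace = model$elbo_trace,
    converged = model$converged, xi = model$xi, eta = model$eta
  )
  jsonlite::write_json(header, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_factor_model
#' @export
read_factor_model <- function(path) {
  gene_scores <- as.matrix(utils::read.table(
    file.path(path, "gene_scores.tsv"), header = TRUE, sep = "\t",
    check.names = FALSE
  ))
  cell_scores <- as.matrix(utils::read.table(
    file.path(path, "cell_scores.tsv"), header = TRUE, sep = "\t",
    check.names = FALSE
  ))
  header <- jsonlite::read_json(file.path(path, "model.json"),
                                simplifyVector = TRUE)
  hyper <- do.call(hpf_hyperparams, header$hyper[
    c("k", "a", "a_prime", "c", "c_prime", "b_prime", "d_prime",
      "max_iter", "tol", "seed")
  ])
  structure(
    list(gene_scores = gene_scores, cell_scores = cell_scores,
         xi = header$xi, eta = header$eta,
         elbo_trace = header$elbo_trace %||% numeric(0),
         hyper = hyper, converged = header$converged),
    class = "factor_model"
  )
}

#' Write / read a spot grid
#'
#' A directory of CSVs: `counts.csv`, `spot_meta.csv` and, when present,
#' `fractions.csv` and `summed_expr.csv`.
#'
#' @param grid A `spot_grid`.
#' @param path Directory.
#' @return `path` (write) or the restored `spot_grid` (read).
#' @export
write_spots <- function(grid, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(grid$counts), file.path(path, "counts.csv"))
  utils::write.csv(grid$spot_meta, file.path(path, "spot_meta.csv"),
                   row.names = FALSE)
  if (!is.null(grid$fractions)) {
    utils::write.csv(as.data.frame(grid$fractions),
                     file.path(path, "fractions.csv"))
  }
  if (!is.null(grid$summed_expr)) {
    utils::write.csv(as.data.frame(grid$summed_expr),
                     file.path(path, "summed_expr.csv"))
  }
  invisible(path)
}

#' @rdname write_spots
#' @export
read_spots <- function(path) {
  counts <- as.matrix(utils::read.csv(file.path(path, "counts.csv"),
                                      row.names = 1, check.names = FALSE))
  meta <- as_tibble(utils::read.csv(file.path(path, "spot_meta.csv"),
                                    stringsAsFactors = FALSE))
  read_opt <- function(name) {
    f <- file.path(path, name)
    if (file.exists(f)) {
      as.matrix(utils::read.csv(f, row.names = 1, check.names = FALSE))
    } else NULL
  }
  spot_grid(counts, meta, fractions = read_opt("fractions.csv"),
            summed_expr = read_opt("summed_expr.csv"))
}

#' Resolved run configuration with the published defaults
#'
#' Central registry of every tunable the pipeline exposes; defaults equal
#' the published analysis values. Overrides may come from a YAML file or a
#' named list; unknown keys are rejected.
#'
#' @param overrides Named list, or path to a YAML file of overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(overrides = NULL) {
  defaults <- list(
    qc_min_umi = 500, qc_min_genes = 250, qc_min_complexity = 0.8,
    qc_max_mito = 0.20, gene_min_cells = 10, spot_min_umi = 1000,
    marker_min_markers = 30, marker_p = 0.05, marker_lfc = 0.25,
    hpf_a = 0.3, hpf_c = 0.3, hpf_a_prime = 1, hpf_c_prime = 1,
    hpf_tol = 1e-5, hpf_max_iter = 500,
    k_mouse_endothelial = 20, k_mouse_fibroblast = 25, k_mouse_myeloid = 25,
    n_restarts = 20, usage_alpha = 0.01, min_robust_corr = 0.8,
    program_n_top = 200, assign_n_sd = 2,
    jaccard_threshold_endothelial = 0.06, jaccard_threshold_fibroblast = 0.07,
    jaccard_threshold_myeloid = 0.07, homology_max_calls = 3,
    treg_min_cells_endothelial = 5, treg_min_cells_fibroblast = 5,
    treg_min_cells_myeloid = 20, treg_exclude_samples = character(0),
    module_n_bins = 24, module_n_ctrl = 100,
    niche_pseudocount = 1, niche_tail = 0.01, niche_fit_pooled = TRUE,
    presence_posterior_cut = 0.70, presence_fraction_floor = 0.001,
    presence_expr_floor = 50, presence_three_component_types = character(0),
    enrich_n_sample = 100, enrich_n_iter = 10000, enrich_correction = "none",
    program_test_adjust = "BH",
    k_states = 7, lesion_min_spots = 6, lesion_merge_pairs = list(),
    immune_response_threshold = 0.10, lattice = "square",
    de_detect_frac = 0.10, de_prefilter_lfc = 0.25,
    de_sig_alpha = 0.01, de_sig_lfc = 0.5,
    zscore_after_restrict = TRUE,
    seed = 1L
  )
  if (is.character(overrides) && length(overrides) == 1) {
    overrides <- yaml::read_yaml(overrides)
  }
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
    }
    defaults[names(overrides)] <- overrides
  }
  structure(defaults, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
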