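#' Assemble a cell-by-gene count matrix with per-cell metadata
#'
#' The basic single-cell container used throughout the package: a non-negative
#' integer matrix with cells in rows and genes in columns, plus a tibble of
#' per-cell metadata carrying at least `cell_id`, `sample_id`, `condition`
#' (a two-level label, conventionally `"ctrl"` / `"perturbed"`), `lineage`
#' and `cluster`.
#'
#' @param counts Integer matrix (cells x genes), or a sparse `Matrix`.
#'   Column names are the gene symbols and must be unique.
#' @param cell_meta Data frame with one row per cell. Missing standard columns
#'   are filled with a single default level.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, cell_meta = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(counts != round(counts))) abort("counts must be integers")
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("g%04d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(colnames(counts))) abort("gene symbols must be unique")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  }
  if (is.null(cell_meta)) cell_meta <- tibble(cell_id = rownames(counts))
  cell_meta <- as_tibble(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) {
    cell_meta$cell_id <- rownames(counts)
  }
  if (nrow(cell_meta) != nrow(counts)) {
    abort("cell_meta must have one row per cell")
  }
  for (col in c("sample_id", "condition", "lineage", "cluster")) {
    if (!col %in% names(cell_meta)) {
      cell_meta[[col]] <- switch(col, condition = "ctrl", "all")
    }
  }
  if (length(unique(cell_meta$condition)) > 2) {
    abort("condition must have at most two levels")
  }
  structure(
    list(counts = counts, cell_meta = cell_meta),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d cells x %d genes; conditions: %s\n",
    nrow(x$counts), ncol(x$counts),
    paste(unique(x$cell_meta$condition), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Genes of a count matrix or factor model
#' @param x Object with a gene dimension.
#' @return Character vector of gene symbols.
#' @export
gene_symbols <- function(x) UseMethod("gene_symbols")

#' @export
gene_symbols.count_matrix <- function(x) colnames(x$counts)

#' @export
gene_symbols.factor_model <- function(x) rownames(x$gene_scores)

#' Long tidy view of a count matrix
#'
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @return Tibble with `cell_id`, `gene`, `count` plus the metadata columns.
#' @export
tidy.count_matrix <- function(x, ...) {
  long <- tibble(
    cell_id = rep(rownames(x$counts), times = ncol(x$counts)),
    gene = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
  left_join(long, x$cell_meta, by = "cell_id")
}

library_sizes <- function(cm) rowSums(cm$counts)

subset_cells <- function(cm, keep) {
  count_matrix(cm$counts[keep, , drop = FALSE],
               cm$cell_meta[keep, , drop = FALSE])
}

subset_genes <- function(cm, keep) {
  count_matrix(cm$counts[, keep, drop = FALSE], cm$cell_meta)
}
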