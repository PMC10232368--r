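#' Library-size log-normalization
#'
#' Divides each cell's counts by its library size, multiplies by a scale
#' factor of 10,000 and takes the natural log of 1 + the result.
#'
#' @param counts A `count_matrix`.
#' @param scale_factor Scale applied after library-size division.
#' @return A `normalized_matrix`: list with `lognorm` (cells x genes) and the
#'   scale factor.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- library_sizes(counts)
  if (any(lib == 0)) {
    abort(sprintf("%d cell(s) have zero library size", sum(lib == 0)))
  }
  structure(
    list(lognorm = log1p(counts$counts / lib * scale_factor),
         scale_factor = scale_factor),
    class = "normalized_matrix"
  )
}

lognorm_matrix <- function(counts, scale_factor = 1e4) {
  lib <- rowSums(counts)
  if (any(lib == 0)) abort("zero-library rows cannot be log-normalized")
  log1p(counts / lib * scale_factor)
}

#' Quality-control filter on cells
#'
#' Retains cells passing all four rules, each a strict inequality: library
#' size above `min_umi`, detected genes above `min_genes`, transcriptomic
#' complexity (log10 genes / log10 UMIs) above `min_complexity`, and
#' mitochondrial fraction below `max_mito`.
#'
#' @param counts A `count_matrix`.
#' @param min_umi,min_genes,min_complexity,max_mito QC cutoffs.
#' @param mito_prefix Prefix identifying mitochondrial genes (e.g. `"mt-"`).
#' @return Filtered `count_matrix`.
#' @export
filter_cells <- function(counts, min_umi = 500, min_genes = 250,
                         min_complexity = 0.8, max_mito = 0.20,
                         mito_prefix = "mt-") {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- library_sizes(counts)
  n_genes <- rowSums(counts$counts > 0)
  complexity <- ifelse(lib > 1, log10(pmax(n_genes, 1)) / log10(lib), 0)
  mito <- startsWith(colnames(counts$counts), mito_prefix)
  mito_frac <- if (any(mito)) {
    rowSums(counts$counts[, mito, drop = FALSE]) / pmax(lib, 1)
  } else {
    rep(0, nrow(counts$counts))
  }
  keep <- lib > min_umi & n_genes > min_genes &
    complexity > min_complexity & mito_frac < max_mito
  if (!any(keep)) abort("cell QC removed every cell")
  subset_cells(counts, keep)
}

#' Filter genes by detection
#'
#' Removes genes detected (count > 0) in fewer than `min_cells` cells.
#'
#' @param counts A `count_matrix`.
#' @param min_cells Minimum number of detecting cells to retain a gene.
#' @return Filtered `count_matrix`.
#' @export
filter_genes <- function(counts, min_cells = 10) {
  stopifnot(inherits(counts, "count_matrix"))
  keep <- colSums(counts$counts > 0) >= min_cells
  if (!any(keep)) abort("gene filter removed every gene")
  subset_genes(counts, keep)
}

#' Filter spatial spots by library size
#'
#' Excludes spots with fewer than `min_umi` UMIs.
#'
#' @param spots A `spot_grid`.
#' @param min_umi Minimum UMI count per spot.
#' @return Filtered `spot_grid`.
#' @export
filter_spots <- function(spots, min_umi = 1000) {
  stopifnot(inherits(spots, "spot_grid"))
  keep <- rowSums(spots$counts) >= min_umi
  if (!any(keep)) abort("spot filter removed every spot")
  spot_grid(
    spots$counts[keep, , drop = FALSE],
    spots$spot_meta[keep, , drop = FALSE],
    fractions = if (!is.null(spots$fractions)) spots$fractions[keep, , drop = FALSE],
    summed_expr = if (!is.null(spots$summed_expr)) spots$summed_expr[keep, , drop = FALSE],
    lognorm = if (!is.null(spots$lognorm)) spots$lognorm[keep, , drop = FALSE]
  )
}

# Vectorized pairwise Welch t-tests between two cell groups, per gene.
# Returns list(p = two-sided p, diff = mean(a) - mean(b)).
welch_by_gene <- function(x_a, x_b) {
  n_a <- nrow(x_a); n_b <- nrow(x_b)
  m_a <- colMeans(x_a); m_b <- colMeans(x_b)
  v_a <- apply(x_a, 2, var); v_b <- apply(x_b, 2, var)
  se2 <- v_a / n_a + v_b / n_b
  t_stat <- (m_a - m_b) / sqrt(se2)
  df <- se2^2 / ((v_a / n_a)^2 / (n_a - 1) + (v_b / n_b)^2 / (n_b - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  p[!is.finite(t_stat)] <- 1
  list(p = p, diff = m_a - m_b)
}

#' Marker selection with iterative merging of indistinct cell types
#'
#' A gene is a marker of a cell type only if, against *every* other type, the
#' pairwise Welch t-test p-value is below `p_thresh` and the mean log-normalized
#' difference exceeds `lfc_thresh`. Types failing to reach `min_markers`
#' markers are merged with their closest neighbor (smallest Euclidean distance
#' between mean log-normalized profiles) and the procedure is repeated until
#' all surviving types have enough markers.
#'
#' @param lognorm Cells x genes log-normalized matrix.
#' @param labels Character vector of per-cell type labels.
#' @param min_markers Minimum markers a retained type must have.
#' @param p_thresh,lfc_thresh Worst-case per-comparison cutoffs.
#' @return A `marker_set`: list with `markers` (tibble: type, gene, worst_p,
#'   worst_lfc), `labels` (the per-cell labels after merging), `merge_history`
#'   (tibble of merges) and `collapsed` flag.
#' @export
select_markers_with_merging <- function(lognorm, labels, min_markers = 30,
                                        p_thresh = 0.05, lfc_thresh = 0.25) {
  labels <- as.character(labels)
  stopifnot(nrow(lognorm) == length(labels))
  if (length(unique(labels)) < 2) abort("need at least two cell-type labels")
  tab <- table(labels)
  if (any(tab < 3)) abort("every label needs at least 3 cells")

  merge_history <- tibble(merged_a = character(), merged_b = character(),
                          new_label = character())
  repeat {
    types <- sort(unique(labels))
    if (length(types) == 1) {
      warn("marker selection collapsed all labels into one type")
      return(structure(
        list(markers = tibble(type = character(), gene = character(),
                              worst_p = double(), worst_lfc = double()),
             labels = labels, merge_history = merge_history, collapsed = TRUE),
        class = "marker_set"
      ))
    }
    groups <- lapply(types, function(t) lognorm[labels == t, , drop = FALSE])
    names(groups) <- types
    # marker table per type: worst (max) p and worst (min) diff over others
    marker_rows <- purrr::map(types, function(t) {
      others <- setdiff(types, t)
      worst_p <- rep(0, ncol(lognorm)); worst_lfc <- rep(Inf, ncol(lognorm))
      for (o in others) {
        w <- welch_by_gene(groups[[t]], groups[[o]])
        worst_p <- pmax(worst_p, w$p)
        worst_lfc <- pmin(worst_lfc, w$diff)
      }
      ok <- worst_p < p_thresh & worst_lfc > lfc_thresh
      tibble(type = t, gene = colnames(lognorm)[ok],
             worst_p = worst_p[ok], worst_lfc = worst_lfc[ok])
    })
    markers <- bind_rows(marker_rows)
    n_markers <- vapply(types, function(t) sum(markers$type == t), integer(1))
    if (all(n_markers >= min_markers)) {
      return(structure(
        list(markers = markers, labels = labels,
             merge_history = merge_history, collapsed = FALSE),
        class = "marker_set"
      ))
    }
    # merge the worst-off type (fewest markers; ties by label order) with its
    # closest neighbor by mean-profile Euclidean distance
    short <- types[which.min(n_markers)]
    profiles <- t(vapply(types, function(t) colMeans(groups[[t]]),
                         numeric(ncol(lognorm))))
    d <- sqrt(rowSums(sweep(profiles, 2, profiles[short, ])^2))
    d[types == short] <- Inf
    neighbor <- types[which.min(d)]
    new_label <- paste(sort(c(short, neighbor)), collapse = "+")
    labels[labels %in% c(short, neighbor)] <- new_label
    merge_history <- bind_rows(
      merge_history,
      tibble(merged_a = short, merged_b = neighbor, new_label = new_label)
    )
  }
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d types, %d markers, %d merges%s\n",
              length(unique(x$labels)), nrow(x$markers),
              nrow(x$merge_history),
              if (x$collapsed) " (collapsed)" else ""))
  invisible(x)
}

#' @export
tidy.marker_set <- function(x, ...) x$markers
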