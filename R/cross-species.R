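#' One-to-one ortholog map between two species' gene symbols
#'
#' @param pairs Data frame with columns `symbol_a` and `symbol_b` (the two
#'   species' gene symbols). Must be injective in both directions.
#' @return An `ortholog_map`.
#' @export
ortholog_map <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!all(c("symbol_a", "symbol_b") %in% names(pairs))) {
    abort("ortholog pairs need columns symbol_a and symbol_b")
  }
  if (!nrow(pairs)) abort("ortholog map is empty")
  if (anyDuplicated(pairs$symbol_a) || anyDuplicated(pairs$symbol_b)) {
    abort("ortholog map must be one-to-one (duplicate symbols found)")
  }
  structure(list(pairs = pairs[, c("symbol_a", "symbol_b")]), class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("<ortholog_map> %d one-to-one pairs\n", nrow(x$pairs)))
  invisible(x)
}

#' @export
tidy.ortholog_map <- function(x, ...) x$pairs

#' Restrict two factor models to their shared ortholog universe
#'
#' Keeps genes with a one-to-one ortholog that carry signal (positive total
#' gene score) in both species, and renames species-B genes to their
#' species-A symbols so downstream set operations work in one namespace.
#'
#' @param model_a,model_b `factor_model` objects of the two species.
#' @param map An [ortholog_map()] (symbol_a in model_a's space).
#' @return List of the two gene-filtered models (`a`, `b`), both indexed by
#'   species-A symbols.
#' @export
restrict_to_orthologs <- function(model_a, model_b, map) {
  stopifnot(inherits(map, "ortholog_map"))
  pairs <- map$pairs %>%
    filter(.data$symbol_a %in% rownames(model_a$gene_scores),
           .data$symbol_b %in% rownames(model_b$gene_scores))
  if (!nrow(pairs)) abort("no mapped genes shared by both models")
  expr_a <- rowSums(model_a$gene_scores[pairs$symbol_a, , drop = FALSE]) > 0
  expr_b <- rowSums(model_b$gene_scores[pairs$symbol_b, , drop = FALSE]) > 0
  pairs <- pairs[expr_a & expr_b, , drop = FALSE]
  if (!nrow(pairs)) abort("no mapped genes expressed in both models")
  a <- model_a; b <- model_b
  a$gene_scores <- a$gene_scores[pairs$symbol_a, , drop = FALSE]
  b$gene_scores <- b$gene_scores[pairs$symbol_b, , drop = FALSE]
  rownames(b$gene_scores) <- pairs$symbol_a
  list(a = a, b = b)
}

#' Assign genes to factors by the mean + 2 SD rule
#'
#' A gene belongs to a factor when its gene score strictly exceeds the mean
#' plus two population standard deviations of that factor's gene scores.
#'
#' @param model A `factor_model`.
#' @param n_sd Number of standard deviations above the mean.
#' @return A `gene_assignment`: named list of character vectors, one per
#'   factor.
#' @export
assign_genes <- function(model, n_sd = 2) {
  scores <- model$gene_scores
  if (nrow(scores) < 3) abort("need at least 3 genes to assign")
  sets <- lapply(seq_len(ncol(scores)), function(f) {
    s <- scores[, f]
    mu <- mean(s)
    sigma <- sqrt(mean((s - mu)^2))   # population SD
    rownames(scores)[s > mu + n_sd * sigma]
  })
  names(sets) <- colnames(scores)
  structure(list(sets = sets, n_sd = n_sd), class = "gene_assignment")
}

#' @export
print.gene_assignment <- function(x, ...) {
  cat(sprintf("<gene_assignment> %d factors; set sizes %s\n",
              length(x$sets),
              paste(lengths(x$sets), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.gene_assignment <- function(x, ...) {
  tibble(
    factor = rep(names(x$sets), lengths(x$sets)),
    gene = unlist(x$sets, use.names = FALSE)
  )
}

#' Jaccard homology between two species' factor assignments
#'
#' Computes the Jaccard similarity (shared / union of assigned genes) for
#' every factor pair, z-scores each species-A factor's column across
#' species-B factors, and calls homologous pairs whose Jaccard exceeds the
#' lineage threshold, keeping at most `max_calls` per species-A factor
#' (highest Jaccard first).
#'
#' @param assign_a,assign_b `gene_assignment`s over the same
#'   (ortholog-restricted) gene universe.
#' @param lineage_threshold Raw Jaccard call threshold (0.06 endothelial,
#'   0.07 fibroblast/myeloid presets).
#' @param max_calls Call cap per species-A factor (`Inf` disables).
#' @return A `homology_matrix`: matrices `J` and `z` (factors_a x factors_b),
#'   tibble `calls` (factor_a, factor_b, jaccard, z), and flags for pairs
#'   where both sets were empty.
#' @export
jaccard_homology <- function(assign_a, assign_b, lineage_threshold = 0.06,
                             max_calls = 3) {
  sa <- assign_a$sets; sb <- assign_b$sets
  J <- matrix(0, length(sa), length(sb),
              dimnames = list(names(sa), names(sb)))
  empty_pair <- J > 1
  for (i in seq_along(sa)) {
    for (j in seq_along(sb)) {
      uni <- union(sa[[i]], sb[[j]])
      if (!length(uni)) {
        J[i, j] <- 0
        empty_pair[i, j] <- TRUE
      } else {
        J[i, j] <- length(intersect(sa[[i]], sb[[j]])) / length(uni)
      }
    }
  }
  if (any(empty_pair)) warn("factor pair(s) with two empty assignments: Jaccard set to 0")
  z <- t(apply(J, 1, function(row) {
    s <- if (length(row) > 1) sd(row) else 0
    if (is.na(s) || s == 0) rep(0, length(row)) else (row - mean(row)) / s
  }))
  if (ncol(J) == 1) z <- matrix(z, nrow(J), 1)
  dimnames(z) <- dimnames(J)
  calls <- tibble(
    factor_a = rep(rownames(J), times = ncol(J)),
    factor_b = rep(colnames(J), each = nrow(J)),
    jaccard = as.vector(J),
    z = as.vector(z)
  ) %>%
    filter(.data$jaccard > lineage_threshold) %>%
    group_by(.data$factor_a) %>%
    arrange(dplyr::desc(.data$jaccard), .by_group = TRUE) %>%
    dplyr::slice_head(n = if (is.finite(max_calls)) max_calls else dplyr::n()) %>%
    ungroup()
  structure(
    list(J = J, z = z, calls = calls, lineage_threshold = lineage_threshold),
    class = "homology_matrix"
  )
}

#' @export
print.homology_matrix <- function(x, ...) {
  cat(sprintf("<homology_matrix> %d x %d factors; %d call(s) at J > %.2f\n",
              nrow(x$J), ncol(x$J), nrow(x$calls), x$lineage_threshold))
  invisible(x)
}

#' @export
tidy.homology_matrix <- function(x, ...) {
  tibble(
    factor_a = rep(rownames(x$J), times = ncol(x$J)),
    factor_b = rep(colnames(x$J), each = nrow(x$J)),
    jaccard = as.vector(x$J),
    z = as.vector(x$z)
  )
}

#' Jaccard heat-map across species' factors
#' @param object A `homology_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.homology_matrix <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$factor_b, y = .data$factor_a,
                           fill = .data$jaccard)) +
    geom_tile() +
    scale_fill_viridis_c(name = "Jaccard") +
    labs(x = "species B factor", y = "species A factor") +
    theme_minimal()
}

#' Normalized gene loadings (fraction of total gene score)
#'
#' Divides each gene's score by the sum of its scores across all factors, so
#' loadings are comparable across factorizations. All-zero genes are
#' excluded with a notice.
#'
#' @param model A `factor_model`.
#' @return Genes x k matrix with unit row sums.
#' @export
normalized_gene_loading <- function(model) {
  scores <- model$gene_scores
  tot <- rowSums(scores)
  if (any(tot == 0)) {
    inform(sprintf("%d all-zero gene(s) excluded from loading normalization",
                   sum(tot == 0)))
    scores <- scores[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  scores / tot
}

#' Genes conserved between homologous factor groups of two species
#'
#' Sums the gene scores of each species' factor group (a biological program
#' may split across factors), re-applies the mean + 2 SD assignment to the
#' summed scores, and returns the genes assigned in both species, in
#' species-A symbols.
#'
#' @param model_a,model_b Ortholog-restricted `factor_model`s (see
#'   [restrict_to_orthologs()]; both in species-A symbols).
#' @param factors_a,factors_b Factor index vectors defining the two groups.
#' @param n_sd Assignment stringency.
#' @return Character vector of conserved genes.
#' @export
conserved_genes <- function(model_a, model_b, factors_a, factors_b, n_sd = 2) {
  group_set <- function(model, fs) {
    s <- rowSums(model$gene_scores[, fs, drop = FALSE])
    mu <- mean(s); sigma <- sqrt(mean((s - mu)^2))
    names(s)[s > mu + n_sd * sigma]
  }
  intersect(group_set(model_a, factors_a), group_set(model_b, factors_b))
}

#' Correlation of factor-group usage with T_reg abundance across samples
#'
#' Per sample, averages the summed cell scores of the factor group over that
#' sample's cells, then computes the Spearman correlation of the log2 mean
#' usage with the log2 T_reg proportion. Samples with too few cells are
#' excluded and listed.
#'
#' @param model A `factor_model`.
#' @param sample_labels Per-cell sample ids (aligned with the model's cells).
#' @param treg_proportion Named per-sample vector in (0, 1].
#' @param factor_group Factor indices whose cell scores are summed.
#' @param min_cells Minimum cells for a sample to enter the correlation.
#' @param exclude_samples Optional sample ids to drop (e.g. flagged outliers);
#'   never automatic.
#' @return List with `rho`, `p`, `per_sample` tibble (sample, n_cells,
#'   mean_usage, treg_proportion, used) .
#' @export
treg_usage_correlation <- function(model, sample_labels, treg_proportion,
                                   factor_group, min_cells = 5,
                                   exclude_samples = character()) {
  scores <- model$cell_scores
  sample_labels <- as.character(sample_labels)
  stopifnot(length(sample_labels) == nrow(scores))
  usage <- rowSums(scores[, factor_group, drop = FALSE])
  per_sample <- tibble(sample = sample_labels, usage = usage) %>%
    group_by(.data$sample) %>%
    summarise(n_cells = n(), mean_usage = mean(.data$usage), .groups = "drop")
  per_sample$treg_proportion <- treg_proportion[per_sample$sample]
  if (any(is.na(per_sample$treg_proportion))) {
    abort("treg_proportion must be named with every sample id")
  }
  per_sample$used <- per_sample$n_cells > min_cells &
    !per_sample$sample %in% exclude_samples
  used <- filter(per_sample, .data$used)
  if (nrow(used) < 5) abort("fewer than 5 usable samples")
  if (sd(used$treg_proportion) == 0) {
    abort("T_reg proportion is constant across samples; correlation undefined")
  }
  excluded <- per_sample$sample[!per_sample$used]
  if (length(excluded)) {
    inform(paste("samples excluded from correlation:", paste(excluded, collapse = ", ")))
  }
  ct <- suppressWarnings(
    cor.test(log2(used$mean_usage), log2(used$treg_proportion),
             method = "spearman")
  )
  list(rho = unname(ct$estimate), p = ct$p.value, per_sample = per_sample)
}
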