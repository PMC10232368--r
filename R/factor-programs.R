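#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test comparing two samples. For group sizes of at most
#' `exact_max` the two-sided p-value is computed by exact enumeration of all
#' group assignments of the pooled values (valid under ties):
#' p = P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|). Larger groups use the
#' normal approximation with tie correction and a 0.5 continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest group size for the enumeration path.
#' @return List with `U` (statistic of `x`), `p`, and `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (max(n1, n2) <= exact_max) {
    sets <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
    return(list(U = u_obs, p = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(U = u_obs, p = NA_real_, method = "degenerate"))
  }
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  list(U = u_obs, p = min(1, 2 * pnorm(-max(z, 0))), method = "normal")
}

#' Average factor usage per cluster and condition, with differential tests
#'
#' Computes the mean cell score of every factor in each cluster under each of
#' the two conditions, min-max normalizes each factor's row of means to
#' [0, 1], and tests each factor in each cluster for a condition difference
#' with a two-sided Mann-Whitney U test on the cell scores.
#'
#' @param model A `factor_model`.
#' @param clusters Per-cell cluster labels (aligned with the model's cells).
#' @param conditions Per-cell condition labels (exactly two levels).
#' @param perturbed Which condition level is the perturbed one; defaults to
#'   `"perturbed"` when present, else the second sorted level.
#' @return A `usage_table`: `means` tibble (factor, cluster, condition,
#'   mean_score, row_norm), `tests` tibble (factor, cluster, U, p,
#'   mean_ctrl, mean_perturbed, flag), and the perturbed level.
#' @export
usage_table <- function(model, clusters, conditions, perturbed = NULL) {
  scores <- model$cell_scores
  clusters <- as.character(clusters); conditions <- as.character(conditions)
  stopifnot(length(clusters) == nrow(scores),
            length(conditions) == nrow(scores))
  cond_levels <- sort(unique(conditions))
  if (length(cond_levels) != 2) abort("usage_table requires exactly two conditions")
  if (is.null(perturbed)) {
    perturbed <- if ("perturbed" %in% cond_levels) "perturbed" else cond_levels[2]
  }
  ctrl <- setdiff(cond_levels, perturbed)
  k <- ncol(scores)
  cluster_levels <- sort(unique(clusters))

  df <- as_tibble(scores, .name_repair = "minimal")
  names(df) <- paste0("f", seq_len(k))
  df$cluster <- clusters
  df$condition <- conditions
  means <- df %>%
    group_by(.data$cluster, .data$condition) %>%
    summarise(across(dplyr::starts_with("f"), mean), .groups = "drop") %>%
    tidyr::pivot_longer(dplyr::starts_with("f"), names_to = "factor",
                        values_to = "mean_score") %>%
    mutate(factor = as.integer(sub("^f", "", .data$factor))) %>%
    tidyr::complete(cluster = cluster_levels, condition = cond_levels,
                    factor = seq_len(k)) %>%
    mutate(missing = is.na(.data$mean_score)) %>%
    select("factor", "cluster", "condition", "mean_score", "missing")
  means <- means %>%
    group_by(.data$factor) %>%
    mutate(row_norm = {
      rng <- range(.data$mean_score, na.rm = TRUE)
      if (diff(rng) == 0) rep(0, length(.data$mean_score))
      else (.data$mean_score - rng[1]) / diff(rng)
    }) %>%
    ungroup()

  tests <- tidyr::expand_grid(factor = seq_len(k), cluster = cluster_levels)
  res <- purrr::pmap(tests, function(factor, cluster) {
    in_cl <- clusters == cluster
    x <- scores[in_cl & conditions == ctrl, factor]
    y <- scores[in_cl & conditions == perturbed, factor]
    if (!length(x) || !length(y)) {
      return(tibble(U = NA_real_, p = NA_real_, mean_ctrl = mean(x),
                    mean_perturbed = mean(y), flag = "missing_condition"))
    }
    mw <- mann_whitney(x, y)
    tibble(U = mw$U, p = mw$p, mean_ctrl = mean(x), mean_perturbed = mean(y),
           flag = if (is.na(mw$p)) "degenerate" else NA_character_)
  })
  tests <- dplyr::bind_cols(tests, bind_rows(res))
  structure(
    list(means = means, tests = tests, perturbed = perturbed, ctrl = ctrl),
    class = "usage_table"
  )
}

#' @export
print.usage_table <- function(x, ...) {
  cat(sprintf("<usage_table> %d factors x %d clusters; perturbed level: %s\n",
              max(x$tests$factor), length(unique(x$tests$cluster)), x$perturbed))
  invisible(x)
}

#' @export
tidy.usage_table <- function(x, ...) {
  left_join(x$means, x$tests, by = c("factor", "cluster"))
}

#' Heat-map of row-normalized factor usage
#' @param object A `usage_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.usage_table <- function(object, ...) {
  df <- object$means %>%
    mutate(group = paste(.data$cluster, .data$condition, sep = " / "))
  ggplot(df, aes(x = .data$group, y = stats::reorder(factor(.data$factor), .data$factor),
                 fill = .data$row_norm)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1), name = "row-normalized\nmean usage") +
    labs(x = "cluster / condition", y = "factor") +
    theme_minimal()
}

#' Select condition-responsive, restart-robust factors
#'
#' A factor is selected when it is differential at `alpha` in at least one
#' cluster (in the required direction) and its restart-stability median
#' matched correlation reaches `min_robust_corr`.
#'
#' @param table A `usage_table`.
#' @param robustness A [restart_robustness()] result, or a tibble with
#'   `factor` and `median_corr` covering every factor.
#' @param alpha Per-test p-value cutoff (no multiplicity correction; the raw
#'   threshold is the selection rule).
#' @param direction `"perturbed_up"` requires the perturbed mean to exceed the
#'   control mean in a significant cluster; `"any"` drops the requirement.
#' @param min_robust_corr Restart-stability floor.
#' @return Sorted integer vector of selected factor indices.
#' @export
select_responsive_factors <- function(table, robustness, alpha = 0.01,
                                      direction = c("perturbed_up", "any"),
                                      min_robust_corr = 0.8) {
  direction <- match.arg(direction)
  rob <- if (inherits(robustness, "restart_robustness")) {
    robustness$factor_corr
  } else {
    as_tibble(robustness)
  }
  k <- max(table$tests$factor)
  if (!all(seq_len(k) %in% rob$factor)) {
    abort("robustness report must cover all factors")
  }
  robust_ok <- rob$factor[rob$median_corr >= min_robust_corr]
  hits <- table$tests %>%
    filter(!is.na(.data$p), .data$p < alpha)
  if (direction == "perturbed_up") {
    hits <- filter(hits, .data$mean_perturbed > .data$mean_ctrl)
  }
  sort(intersect(unique(hits$factor), robust_ok))
}

#' Genes most correlated with a factor's usage on a cell subset
#'
#' Pearson-correlates each gene's log-normalized expression with the factor's
#' cell scores over the chosen subset and returns the top `n_top` genes.
#' Genes with constant expression in the subset are excluded with a notice.
#'
#' @param model A `factor_model`.
#' @param lognorm Cells x genes log-normalized matrix aligned with the
#'   model's cells.
#' @param subset_cells Logical mask, integer indices, or cell ids selecting
#'   the subset (at least `min_cells` cells).
#' @param factor_id Factor index.
#' @param n_top Program length cap.
#' @param min_cells Minimum subset size.
#' @return A `gene_program`: tibble `genes` (gene, correlation, rank) plus
#'   `factor_id` and `n_cells`.
#' @export
factor_gene_program <- function(model, lognorm, subset_cells, factor_id,
                                n_top = 200, min_cells = 30) {
  scores <- model$cell_scores
  stopifnot(nrow(lognorm) == nrow(scores))
  if (is.character(subset_cells)) {
    subset_cells <- rownames(scores) %in% subset_cells
  }
  sub_expr <- lognorm[subset_cells, , drop = FALSE]
  sub_score <- scores[subset_cells, factor_id]
  if (nrow(sub_expr) < min_cells) {
    abort(sprintf("subset has %d cells; at least %d required",
                  nrow(sub_expr), min_cells))
  }
  if (sd(sub_score) == 0) abort("factor scores are constant on the subset")
  keep <- apply(sub_expr, 2, sd) > 0
  if (any(!keep)) {
    inform(sprintf("%d constant gene(s) excluded from correlation", sum(!keep)))
  }
  corr <- as.vector(cor(sub_expr[, keep, drop = FALSE], sub_score))
  ord <- order(corr, decreasing = TRUE)
  top <- head(ord, n_top)
  structure(
    list(genes = tibble(gene = colnames(sub_expr)[keep][top],
                        correlation = corr[top],
                        rank = seq_along(top)),
         factor_id = factor_id, n_cells = nrow(sub_expr)),
    class = "gene_program"
  )
}

#' @export
print.gene_program <- function(x, ...) {
  cat(sprintf("<gene_program> factor %s: %d genes from %d cells (top: %s)\n",
              x$factor_id, nrow(x$genes), x$n_cells,
              paste(head(x$genes$gene, 3), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.gene_program <- function(x, ...) x$genes

#' Genes shared between two factor-associated programs
#'
#' Intersects two ranked gene programs, translating the second through an
#' ortholog map when the programs live in different species' gene spaces, and
#' orders the shared genes by mean rank.
#'
#' @param program_a,program_b `gene_program` objects.
#' @param ortholog_map Optional [ortholog_map()] from species A to species B.
#' @return Tibble (gene, rank_a, rank_b, mean_rank), ordered by mean rank.
#' @export
shared_program <- function(program_a, program_b, ortholog_map = NULL) {
  if (!nrow(program_a$genes) || !nrow(program_b$genes)) {
    abort("both programs must be non-empty")
  }
  genes_b <- program_b$genes$gene
  if (!is.null(ortholog_map)) {
    translated <- ortholog_map$pairs$symbol_a[match(genes_b, ortholog_map$pairs$symbol_b)]
    genes_b <- ifelse(is.na(translated), genes_b, translated)
  }
  shared <- intersect(program_a$genes$gene, genes_b)
  tibble(
    gene = shared,
    rank_a = program_a$genes$rank[match(shared, program_a$genes$gene)],
    rank_b = program_b$genes$rank[match(shared, genes_b)]
  ) %>%
    mutate(mean_rank = (.data$rank_a + .data$rank_b) / 2) %>%
    arrange(.data$mean_rank)
}
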