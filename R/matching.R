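# Minimum-cost perfect assignment (Jonker-Volgenant style shortest augmenting
# paths with potentials). cost: square numeric matrix. Returns for each row the
# assigned column. O(n^3); factor counts here are <= ~30.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), all(is.finite(cost)))
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1]] <- j
  assignment
}

factor_correlation_matrix <- function(a, b) {
  if (any(apply(a, 2, sd) == 0) || any(apply(b, 2, sd) == 0)) {
    abort("constant score vector: factor correlation undefined")
  }
  cor(a, b)
}

#' Match factors between two models by Hungarian assignment
#'
#' Pairs factors of two models by minimum-cost perfect matching under cost
#' 1 - Pearson correlation of their score vectors. With unequal factor
#' counts, min(k_A, k_B) pairs are matched (the cost matrix is padded with a
#' constant, which leaves the optimal real pairing unchanged).
#'
#' @param model_a,model_b `factor_model` objects.
#' @param on Score matrix used for the correlation: `"gene"` (default; the two
#'   models must share a gene universe), `"cell"`, or `"both"` (average of the
#'   two correlations).
#' @return A `factor_match`: tibble `pairs` (factor_a, factor_b, corr_gene,
#'   corr_cell, corr), `median_corr`, and `total_cost`.
#' @export
match_factors <- function(model_a, model_b, on = c("gene", "cell", "both")) {
  on <- match.arg(on)
  corr_gene <- corr_cell <- NULL
  if (on %in% c("gene", "both")) {
    shared <- intersect(rownames(model_a$gene_scores), rownames(model_b$gene_scores))
    if (length(shared) < 3) abort("gene-based matching needs a shared gene universe")
    corr_gene <- factor_correlation_matrix(
      model_a$gene_scores[shared, , drop = FALSE],
      model_b$gene_scores[shared, , drop = FALSE]
    )
  }
  if (on %in% c("cell", "both")) {
    if (nrow(model_a$cell_scores) != nrow(model_b$cell_scores)) {
      abort("cell-based matching needs the same cells in both models")
    }
    corr_cell <- factor_correlation_matrix(model_a$cell_scores, model_b$cell_scores)
  }
  corr <- switch(on, gene = corr_gene, cell = corr_cell,
                 both = (corr_gene + corr_cell) / 2)
  k_a <- nrow(corr); k_b <- ncol(corr)
  n <- max(k_a, k_b)
  cost <- matrix(0, n, n)
  cost[seq_len(k_a), seq_len(k_b)] <- 1 - corr
  assignment <- solve_assignment(cost)
  pairs <- tibble(factor_a = seq_len(k_a), factor_b = assignment[seq_len(k_a)])
  pairs <- pairs[pairs$factor_b <= k_b, , drop = FALSE]
  pairs$corr_gene <- if (!is.null(corr_gene)) {
    corr_gene[cbind(pairs$factor_a, pairs$factor_b)]
  } else NA_real_
  pairs$corr_cell <- if (!is.null(corr_cell)) {
    corr_cell[cbind(pairs$factor_a, pairs$factor_b)]
  } else NA_real_
  pairs$corr <- corr[cbind(pairs$factor_a, pairs$factor_b)]
  structure(
    list(pairs = pairs, median_corr = median(pairs$corr),
         total_cost = sum(1 - pairs$corr), on = on),
    class = "factor_match"
  )
}

#' @export
print.factor_match <- function(x, ...) {
  cat(sprintf("<factor_match> %d pairs (on %s scores); median correlation %.3f\n",
              nrow(x$pairs), x$on, x$median_corr))
  invisible(x)
}

#' @export
tidy.factor_match <- function(x, ...) x$pairs

#' Stability of factors across random restarts
#'
#' Refits the model `n_restarts` times with distinct seeds and
#' Hungarian-matches every pair of fits; the median matched correlation per
#' pair summarizes how reproducible the factorization is.
#'
#' @param counts A `count_matrix`.
#' @param hyper `hpf_hyperparams`; restart r uses seed `hyper$seed + r - 1`.
#' @param n_restarts Number of fits (>= 2).
#' @param on Passed to [match_factors()].
#' @return A `restart_robustness` object: tibble `pair_medians`
#'   (restart_a, restart_b, median_corr), per-factor summary `factor_corr`
#'   (median best-match correlation of each baseline factor across restarts),
#'   and the list of fitted models.
#' @export
restart_robustness <- function(counts, hyper, n_restarts = 20,
                               on = c("gene", "cell", "both")) {
  on <- match.arg(on)
  if (n_restarts < 2) abort("n_restarts must be at least 2")
  models <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    h <- hyper; h$seed <- hyper$seed + r - 1L
    models[[r]] <- tryCatch(fit_hpf(counts, h), error = function(e) {
      abort(sprintf("restart %d failed: %s", r, conditionMessage(e)))
    })
  }
  combos <- combn(n_restarts, 2)
  rows <- vector("list", ncol(combos))
  per_factor <- matrix(NA_real_, hyper$k, n_restarts - 1)
  for (m in seq_len(ncol(combos))) {
    i <- combos[1, m]; j <- combos[2, m]
    fm <- match_factors(models[[i]], models[[j]], on = on)
    rows[[m]] <- tibble(restart_a = i, restart_b = j,
                        median_corr = fm$median_corr)
    if (i == 1) per_factor[fm$pairs$factor_a, j - 1] <- fm$pairs$corr
  }
  structure(
    list(pair_medians = bind_rows(rows),
         factor_corr = tibble(
           factor = seq_len(hyper$k),
           median_corr = apply(per_factor, 1, median, na.rm = TRUE)
         ),
         models = models, on = on),
    class = "restart_robustness"
  )
}

#' @export
print.restart_robustness <- function(x, ...) {
  cat(sprintf(
    "<restart_robustness> %d restart pairs; pairwise medians %.3f-%.3f\n",
    nrow(x$pair_medians), min(x$pair_medians$median_corr),
    max(x$pair_medians$median_corr)
  ))
  invisible(x)
}

#' @export
tidy.restart_robustness <- function(x, ...) x$pair_medians

#' Robustness of chosen factors to the number of factors
#'
#' Refits at each k in `k_range` (`n_reps` seeds each), Hungarian-matches each
#' fit to the baseline model, and reports the mean best-match correlation of
#' every factor of interest.
#'
#' @param counts A `count_matrix`.
#' @param hyper Baseline hyperparameters (k is overridden per refit).
#' @param baseline The reference `factor_model`.
#' @param k_range Integer vector of factor counts to scan.
#' @param n_reps Fits per k.
#' @param factors_of_interest Baseline factor indices to track (may be empty).
#' @param on Passed to [match_factors()].
#' @return Tibble (k, factor, mean_corr).
#' @export
k_robustness <- function(counts, hyper, baseline, k_range, n_reps = 20,
                         factors_of_interest = seq_len(ncol(baseline$gene_scores)),
                         on = c("gene", "cell", "both")) {
  on <- match.arg(on)
  if (!length(k_range)) abort("k_range must be non-empty")
  k_base <- ncol(baseline$gene_scores)
  if (length(factors_of_interest) &&
      any(factors_of_interest < 1 | factors_of_interest > k_base)) {
    abort("factors_of_interest outside the baseline factor range")
  }
  if (!length(factors_of_interest)) {
    return(tibble(k = integer(), factor = integer(), mean_corr = double()))
  }
  rows <- list()
  for (k in k_range) {
    corr_acc <- matrix(NA_real_, length(factors_of_interest), n_reps)
    for (r in seq_len(n_reps)) {
      h <- hyper; h$k <- as.integer(k); h$seed <- hyper$seed + 1000L * match(k, k_range) + r
      fm <- match_factors(baseline, fit_hpf(counts, h), on = on)
      idx <- match(factors_of_interest, fm$pairs$factor_a)
      corr_acc[, r] <- fm$pairs$corr[idx]
    }
    rows[[length(rows) + 1]] <- tibble(
      k = k, factor = factors_of_interest,
      mean_corr = rowMeans(corr_acc, na.rm = TRUE)
    )
  }
  bind_rows(rows)
}

#' Fraction of a cell's score mass in its top factors
#'
#' @param model A `factor_model`.
#' @param top_n Number of leading factors per cell.
#' @return Per-cell numeric vector in (0, 1].
#' @export
topmass_fraction <- function(model, top_n = 7) {
  scores <- model$cell_scores
  if (ncol(scores) <= top_n) return(rep(1, nrow(scores)))
  apply(scores, 1, function(s) {
    sum(sort(s, decreasing = TRUE)[seq_len(top_n)]) / sum(s)
  })
}

#' Choose the number of factors by top-factor mass concentration
#'
#' Fits the model over a grid of k and computes, per k, the average per-cell
#' fraction of total cell-score mass concentrated in the `top_n` largest
#' factors. The chosen k is the largest one whose average fraction still
#' meets `target` — the most granular factorization in which a handful of
#' programs explains most of each cell's usage.
#'
#' @param counts A `count_matrix`.
#' @param hyper `hpf_hyperparams` (k overridden per grid point).
#' @param k_grid Ascending integer grid with min(k_grid) > top_n.
#' @param top_n Leading factors per cell.
#' @param target Required average top-mass fraction.
#' @return List with `chosen_k`, `diagnostics` tibble (k, mean_topmass),
#'   `target_met` flag (FALSE = no k met the target and the max-diagnostic k
#'   was returned with a warning).
#' @export
select_k_topmass <- function(counts, hyper, k_grid, top_n = 7, target = 0.90) {
  stopifnot(length(k_grid) >= 1, !is.unsorted(k_grid))
  if (min(k_grid) <= top_n) abort("min(k_grid) must exceed top_n")
  diag <- purrr::map_dbl(k_grid, function(k) {
    h <- hyper; h$k <- as.integer(k)
    mean(topmass_fraction(fit_hpf(counts, h), top_n = top_n))
  })
  ok <- diag >= target
  if (any(ok)) {
    chosen <- max(k_grid[ok]); met <- TRUE
  } else {
    warn("no k in the grid met the top-mass target; returning max-diagnostic k")
    chosen <- k_grid[which.max(diag)]; met <- FALSE
  }
  list(chosen_k = chosen,
       diagnostics = tibble(k = k_grid, mean_topmass = diag),
       target_met = met)
}

#' Preset k-grid in the style used for human lineages
#'
#' Nine consecutive factor counts starting two above the number of clusters
#' in the lineage.
#'
#' @param n_clusters Cluster count of the lineage.
#' @return Integer vector of length 9.
#' @export
k_grid_preset <- function(n_clusters) as.integer(n_clusters) + 2L + 0:8
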