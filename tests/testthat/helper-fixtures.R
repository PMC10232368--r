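# Small fixtures shared across test files; everything is generated in code.

tiny_counts <- function(seed = 42, n_cells = 60, n_genes = 40) {
  set.seed(seed)
  y <- matrix(rpois(n_cells * n_genes, lambda = 3), n_cells, n_genes)
  colnames(y) <- sprintf("g%03d", seq_len(n_genes))
  rownames(y) <- sprintf("c%03d", seq_len(n_cells))
  count_matrix(y, tibble::tibble(
    cell_id = rownames(y),
    sample_id = rep(c("s1", "s2"), length.out = n_cells),
    condition = rep(c("ctrl", "perturbed"), length.out = n_cells),
    lineage = "sim",
    cluster = rep(c("cl1", "cl2"), length.out = n_cells)
  ))
}

truth_model <- function(truth) {
  factor_model_from_scores(truth$true_gene_scores, truth$true_cell_scores)
}

# brute-force two-sided Mann-Whitney p by enumeration of group assignments
enumerate_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  mu <- n1 * n2 / 2
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  sets <- utils::combn(n1 + n2, n1)
  mean(apply(sets, 2, function(idx) abs(u_of(idx) - mu) >= obs - 1e-12))
}

# textbook BH step-up
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# flood fill connected components on labeled grid spots
flood_fill_components <- function(meta, labels, lattice = "square") {
  n <- nrow(meta)
  comp <- rep(NA_integer_, n)
  nb <- function(i) {
    which(
      meta$section_id == meta$section_id[i] &
        nichefactor:::lattice_neighbors(meta$array_row[i], meta$array_col[i],
                                        meta$array_row, meta$array_col,
                                        lattice) &
        labels == labels[i]
    )
  }
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      j <- stack[[1]]; stack <- stack[-1]
      if (!is.na(comp[j])) next
      comp[j] <- cur
      stack <- c(stack, nb(j)[is.na(comp[nb(j)])])
    }
  }
  comp
}

# all permutations of 1..n (small n only)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub), n - 1))
  }))
}

f1_score <- function(called, truth) {
  tp <- sum(called & truth)
  if (tp == 0) return(0)
  prec <- tp / sum(called)
  rec <- tp / sum(truth)
  2 * prec * rec / (prec + rec)
}
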