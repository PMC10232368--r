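test_that("ortholog restriction filters both models to the shared expressed universe", {
  base <- simulate_hpf_counts(50, 100, 4, seed = 1)
  pair <- simulate_cross_species_pair(base$truth, 2, ortholog_fraction = 0.5,
                                      seeds = c(2L, 3L))
  ma <- truth_model(pair$truth_a); mb <- truth_model(pair$truth_b)
  res <- restrict_to_orthologs(ma, mb, pair$map)
  expect_equal(nrow(res$a$gene_scores), nrow(res$b$gene_scores))
  expect_lte(nrow(res$a$gene_scores), 50)
  expect_identical(rownames(res$a$gene_scores), rownames(res$b$gene_scores))
  # identity map over identical gene sets leaves models unchanged
  idmap <- ortholog_map(tibble::tibble(symbol_a = rownames(ma$gene_scores),
                                       symbol_b = rownames(ma$gene_scores)))
  same <- restrict_to_orthologs(ma, ma, idmap)
  expect_equal(same$a$gene_scores, ma$gene_scores)
  empty_map <- ortholog_map(tibble::tibble(symbol_a = "nope", symbol_b = "nada"))
  expect_error(restrict_to_orthologs(ma, mb, empty_map), "shared")
})

test_that("gene assignment applies the mean + 2 SD rule with population SD", {
  # 99 zeros and one 10: mean 0.1, population sd ~0.995, cut ~2.09 < 10
  scores <- matrix(c(rep(0, 99), 10), 100, 1,
                   dimnames = list(sprintf("g%03d", 1:100), "factor_1"))
  model <- factor_model_from_scores(scores, matrix(1, 5, 1))
  expect_identical(assign_genes(model)$sets$factor_1, "g100")
  # constant scores: sd 0, strict inequality -> nothing assigned
  const <- factor_model_from_scores(matrix(1, 50, 1), matrix(1, 5, 1))
  expect_length(assign_genes(const)$sets[[1]], 0)
  # two symmetric outliers both assigned
  sym <- matrix(c(rep(0, 98), 10, 10), 100, 1,
                dimnames = list(sprintf("g%03d", 1:100), "factor_1"))
  m2 <- factor_model_from_scores(sym, matrix(1, 5, 1))
  expect_setequal(m2 |> assign_genes() |> _$sets[[1]], c("g099", "g100"))
  # invariance to positive rescaling
  m3 <- factor_model_from_scores(scores * 37.5, matrix(1, 5, 1))
  expect_identical(assign_genes(m3)$sets, assign_genes(model)$sets)
})

test_that("Jaccard homology equals a brute-force oracle and applies the call rules", {
  set.seed(50)
  universe <- sprintf("g%03d", 1:200)
  rand_sets <- function(k) {
    sets <- lapply(seq_len(k), function(i) sample(universe, sample(5:40, 1)))
    names(sets) <- paste0("factor_", seq_len(k))
    structure(list(sets = sets, n_sd = 2), class = "gene_assignment")
  }
  a <- rand_sets(6); b <- rand_sets(8)
  hm <- jaccard_homology(a, b, lineage_threshold = 0.06)
  for (i in 1:6) {
    for (j in 1:8) {
      expected <- length(intersect(a$sets[[i]], b$sets[[j]])) /
        length(union(a$sets[[i]], b$sets[[j]]))
      expect_equal(hm$J[i, j], expected, tolerance = 1e-15)
    }
  }
  # worked arithmetic: |A|=40, |B|=40, overlap 20 -> J = 1/3
  a2 <- structure(list(sets = list(f1 = universe[1:40])), class = "gene_assignment")
  b2 <- structure(list(sets = list(f1 = universe[21:60])), class = "gene_assignment")
  expect_equal(jaccard_homology(a2, b2)$J[1, 1], 1 / 3, tolerance = 1e-15)
  # identical assignments give J = 1 on the diagonal
  expect_equal(diag(jaccard_homology(a, a)$J), rep(1, 6), ignore_attr = TRUE)
  # call cap: at most max_calls per species-A factor
  expect_lte(max(table(jaccard_homology(a, b, 0, max_calls = 3)$calls$factor_a)), 3)
  # both-empty pair flagged with J = 0
  e <- structure(list(sets = list(f1 = character(0))), class = "gene_assignment")
  expect_warning(he <- jaccard_homology(e, e), "empty")
  expect_equal(he$J[1, 1], 0)
})

test_that("planted shared programs are called with precision and recall 1", {
  base <- simulate_hpf_counts(100, 300, 5, seed = 60)
  pair <- simulate_cross_species_pair(base$truth, 2, ortholog_fraction = 1,
                                      seeds = c(61L, 62L))
  res <- restrict_to_orthologs(truth_model(pair$truth_a),
                               truth_model(pair$truth_b), pair$map)
  hm <- jaccard_homology(assign_genes(res$a), assign_genes(res$b),
                         lineage_threshold = 0.06)
  called <- paste(hm$calls$factor_a, hm$calls$factor_b)
  expect_setequal(called, c("factor_1 factor_1", "factor_2 factor_2"))
  # z of a matched pair is bounded by (k-1)/sqrt(k) across the comparison
  # factors, so z > 2 needs a wider factorization than k = 5
  base8 <- simulate_hpf_counts(100, 500, 8, seed = 63)
  pair8 <- simulate_cross_species_pair(base8$truth, 2, seeds = c(64L, 65L))
  res8 <- restrict_to_orthologs(truth_model(pair8$truth_a),
                                truth_model(pair8$truth_b), pair8$map)
  hm8 <- jaccard_homology(assign_genes(res8$a), assign_genes(res8$b), 0.06)
  expect_true(all(hm8$calls$z > 2))
})

test_that("normalized gene loadings sum to one per gene", {
  sim <- simulate_hpf_counts(40, 80, 4, seed = 3)
  model <- truth_model(sim$truth)
  nl <- normalized_gene_loading(model)
  expect_equal(unname(rowSums(nl)), rep(1, nrow(nl)), tolerance = 1e-12)
  # k = 1: every fraction is 1; equal scores over k = 4 give 0.25
  one <- factor_model_from_scores(matrix(2, 10, 1), matrix(1, 5, 1))
  expect_true(all(normalized_gene_loading(one) == 1))
  eq <- factor_model_from_scores(matrix(3, 10, 4), matrix(1, 5, 4))
  expect_true(all(normalized_gene_loading(eq) == 0.25))
  withzero <- factor_model_from_scores(rbind(matrix(1, 9, 2), 0), matrix(1, 5, 2))
  expect_message(nz <- normalized_gene_loading(withzero), "excluded")
  expect_equal(nrow(nz), 9)
})

test_that("conserved genes are the intersection of summed-group assignments", {
  set.seed(70)
  n_genes <- 200
  genes <- sprintf("g%03d", 1:n_genes)
  # plant a conserved 25-gene program on factor 1 of both species
  mk <- function(seed) {
    set.seed(seed)
    m <- matrix(rgamma(n_genes * 3, 0.2), n_genes, 3,
                dimnames = list(genes, paste0("factor_", 1:3)))
    m[1:25, 1] <- m[1:25, 1] + 10
    factor_model_from_scores(m, matrix(1, 5, 3))
  }
  a <- mk(71); b <- mk(72)
  got <- conserved_genes(a, b, factors_a = 1, factors_b = 1)
  expect_setequal(got, genes[1:25])
  # disjoint programs are empty
  b2 <- mk(72)
  b2$gene_scores[1:25, 1] <- 0
  b2$gene_scores[100:124, 1] <- 20
  expect_length(intersect(conserved_genes(a, b2, 1, 1), genes[1:25]), 0)
})

test_that("T_reg usage correlation excludes small samples and validates degenerate input", {
  sim <- simulate_treg_cohort(12, responsive_factors = 1, rho_target = -0.8,
                              n_cells_per_sample = 30, n_genes = 20, seed = 80)
  model <- truth_model(sim$truth)
  labels <- sim$counts$cell_meta$sample_id
  # shrink one sample below min_cells and check it is excluded
  keep <- !(labels == "sample01" & seq_along(labels) %% 30 != 0)
  model_small <- factor_model_from_scores(model$gene_scores,
                                          model$cell_scores[keep, ])
  expect_message(
    res <- treg_usage_correlation(model_small, labels[keep],
                                  sim$treg_proportion, 1, min_cells = 20),
    "sample01"
  )
  expect_false(res$per_sample$used[res$per_sample$sample == "sample01"])
  expect_lt(res$rho, 0)
  const <- setNames(rep(0.2, 12), names(sim$treg_proportion))
  expect_error(
    suppressMessages(treg_usage_correlation(model, labels, const, 1)),
    "constant"
  )
  few <- sim$treg_proportion
  expect_error(
    suppressMessages(
      treg_usage_correlation(model, labels, few, 1, min_cells = 1e6)
    ),
    "5 usable"
  )
})
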