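test_that("shared niche genes are the triple intersection", {
  s <- sprintf("g%02d", 1:50)
  expect_setequal(shared_niche_genes(list(s, s, s)), s)
  a <- c("x", "y"); b <- c("y", "z"); c3 <- c("z", "x")
  expect_warning(out <- shared_niche_genes(list(a, b, c3)), "no gene")
  expect_length(out, 0)
})

test_that("module scores are centered on matched controls and shift with planted signal", {
  set.seed(90)
  n_spots <- 300; n_genes <- 1200
  # genes differ in baseline abundance, as in real data, so a condition
  # shift does not re-bin the program genes into program-dominated bins
  gene_base <- rnorm(n_genes, 2, 1.5)
  lognorm <- matrix(rnorm(n_spots * n_genes, 0, 0.5), n_spots, n_genes) +
    matrix(gene_base, n_spots, n_genes, byrow = TRUE)
  colnames(lognorm) <- sprintf("g%04d", seq_len(n_genes))
  gene_set <- sprintf("g%04d", sample(n_genes, 25))
  ms <- module_score(lognorm, gene_set, seed = 1)
  expect_lt(abs(mean(ms$score)), 0.1)
  # +1 added to program genes in a small spot block shifts the score by ~+1
  # there (a small block keeps gene means, hence binning, essentially fixed)
  block <- 1:15
  shifted <- lognorm
  shifted[block, gene_set] <- shifted[block, gene_set] + 1
  ms2 <- module_score(shifted, gene_set, seed = 1)
  expect_lt(abs(mean(ms2$score[block]) - 1), 0.15)
  expect_lt(abs(mean(ms2$score[-block])), 0.1)
  # invariant to adding a spot-constant to all genes
  ms3 <- module_score(lognorm + 5, gene_set, seed = 1)
  expect_equal(ms3$score, ms$score, tolerance = 1e-10)
  expect_error(module_score(lognorm, character(0)), "empty")
  expect_error(module_score(lognorm, "not_a_gene"), "absent")
})

test_that("gamma MLE and tail threshold recover simulated gamma parameters", {
  set.seed(91)
  x <- rgamma(10000, shape = 2, rate = 1)
  fit <- nichefactor:::gamma_mle(x)
  expect_lt(abs(fit$shape - 2) / 2, 0.05)
  expect_lt(abs(fit$rate - 1), 0.05)
  # agreement with the reference ML fitter
  ref <- suppressWarnings(MASS::fitdistr(x, "gamma"))
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-4)
  expect_equal(fit$rate, unname(ref$estimate["rate"]), tolerance = 1e-4)

  scores <- x - 1   # module-score scale; +1 pseudocount restores the gamma
  thr <- gamma_tail_threshold(scores, pseudocount = 1, tail = 0.01)
  analytic_cut <- qgamma(0.99, 2, 1) - 1
  expect_lt(abs(thr$cut - analytic_cut), 0.15)
  frac_above <- mean(scores > thr$cut)
  expect_lt(abs(frac_above - 0.01), 0.004)
  # tail = 0.5 puts the cut at the fitted median minus the pseudocount
  thr50 <- gamma_tail_threshold(scores, 1, tail = 0.5)
  expect_equal(thr50$cut, qgamma(0.5, thr50$shape, thr50$rate) - 1,
               tolerance = 1e-12)
  expect_error(gamma_tail_threshold(rep(-2, 100)), "non-positive")
  expect_error(gamma_tail_threshold(rep(0.5, 100)), "constant")
  expect_error(gamma_tail_threshold(rnorm(10) + 10), "50 spots")
})

test_that("niche calls are independent, non-exclusive thresholdings", {
  ic <- c(0.1, 2, 3, 0.2); ifn <- c(2.5, 0.1, 3, 0.2)
  calls <- call_niches(ic, ifn, ic_threshold = 1, ifn_threshold = 1)
  expect_identical(calls$ic, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(calls$ifn, c(TRUE, FALSE, TRUE, FALSE))
  none <- call_niches(c(0, 0), c(0, 0), 1, 1)
  expect_false(any(none$ic | none$ifn))
})

test_that("planted niches are recovered end-to-end with F1 at least 0.8", {
  sim <- simulate_spot_grid(seed = 92)
  lognorm <- nichefactor:::lognorm_matrix(sim$grid$counts)
  ic_ms <- module_score(lognorm, sim$truth$ic_genes, seed = 1)
  ifn_ms <- module_score(lognorm, sim$truth$ifn_genes, seed = 2)
  ic_thr <- gamma_tail_threshold(ic_ms)
  ifn_thr <- gamma_tail_threshold(ifn_ms)
  calls <- call_niches(ic_ms, ifn_ms, ic_thr, ifn_thr)
  expect_gte(f1_score(calls$ic, sim$truth$niche_mask_ic), 0.8)
  expect_gte(f1_score(calls$ifn, sim$truth$niche_mask_ifn), 0.8)
})

test_that("zero effect sizes make niche calls a ~1% tail artifact", {
  sim <- simulate_spot_grid(seed = 93,
                            niche_spec = list(ic_effect = 0, ifn_effect = 0))
  lognorm <- nichefactor:::lognorm_matrix(sim$grid$counts)
  ms <- module_score(lognorm, sim$truth$ic_genes, seed = 3)
  thr <- gamma_tail_threshold(ms)
  expect_lt(abs(mean(ms$score > thr$cut) - 0.01), 0.012)
})

test_that("presence binarization recovers a planted two-gamma mixture above 95% accuracy", {
  set.seed(94)
  n_spots <- 400
  present <- rep(c(TRUE, FALSE), c(150, 250))
  frac_type <- ifelse(present, rgamma(n_spots, 5, 50), rgamma(n_spots, 2, 2000))
  expr_type <- ifelse(present, rnorm(n_spots, 500, 100), rnorm(n_spots, 20, 5))
  other <- 1 - frac_type
  fractions <- cbind(typeA = frac_type, other = other)
  summed <- cbind(typeA = pmax(expr_type, 1), other = 1000 - expr_type)
  meta <- tibble::tibble(spot_id = sprintf("s%03d", 1:n_spots),
                         array_row = rep(1:20, 20), array_col = rep(1:20, each = 20),
                         section_id = "sec1")
  grid <- spot_grid(matrix(5L, n_spots, 4), meta, fractions = fractions,
                    summed_expr = summed)
  pm <- binarize_presence(grid)
  acc <- mean(pm$mask[, "typeA"] == present)
  expect_gte(acc, 0.95)
})

test_that("floor rules reset sub-floor thresholds exactly", {
  set.seed(95)
  n_spots <- 300
  present <- rep(c(TRUE, FALSE), c(120, 180))
  # both mixture components sit far below the floors
  frac <- ifelse(present, rgamma(n_spots, 40, 80000), rgamma(n_spots, 4, 80000))
  expr <- ifelse(present, rnorm(n_spots, 10, 1), rnorm(n_spots, 2, 0.5))
  fractions <- cbind(t1 = frac, rest = 1 - frac)
  meta <- tibble::tibble(spot_id = sprintf("s%03d", 1:n_spots),
                         array_row = rep(1:15, 20), array_col = rep(1:20, each = 15),
                         section_id = "sec1")
  grid <- spot_grid(matrix(1L, n_spots, 2), meta, fractions = fractions,
                    summed_expr = cbind(t1 = pmax(expr, 0.1), rest = 100))
  pm <- binarize_presence(grid)
  expect_identical(pm$thresholds$fraction_cut[1], 0.001)
  expect_identical(pm$thresholds$expr_cut[1], 50)
  expect_false(any(pm$mask[, "t1"]))   # everything below the floors
})

test_that("enrichment matches exhaustive permutation on tiny instances and planted 2x gives log2 of 1", {
  fractions <- matrix(c(seq(0.1, 0.8, length.out = 8)), 8, 1,
                      dimnames = list(paste0("s", 1:8), "t"))
  fractions <- cbind(fractions, 1 - fractions)
  colnames(fractions) <- c("t", "rest")
  niche <- c(5, 6, 7)
  res <- niche_enrichment(fractions, niche, n_sample = 3, n_iter = 1e5, seed = 7)
  # exact permutation p over all C(8,3) subsets
  subsets <- utils::combn(8, 3)
  null_means <- apply(subsets, 2, function(s) mean(fractions[s, "t"]))
  exact_p <- mean(null_means > mean(fractions[niche, "t"]))
  expect_lt(abs(res$empirical_p[1] - exact_p), 0.01)

  # planted 2x enrichment (niche small next to the background, since its
  # doubled spots also enter the empirical grand mean)
  set.seed(96)
  fr <- matrix(rbeta(1000, 5, 45), 1000, 1, dimnames = list(NULL, "t"))
  niche2 <- 1:60
  fr[niche2, 1] <- fr[niche2, 1] * 2
  fr <- cbind(fr, 1 - fr); colnames(fr) <- c("t", "rest")
  res2 <- niche_enrichment(fr, niche2, n_sample = 100, n_iter = 2000, seed = 8)
  expect_lt(abs(res2$log2_enrichment[1] - 1), 0.2)
  # a niche mean below every null mean gives empirical p = 1
  low <- which(fr[, "t"] <= quantile(fr[, "t"], 0.1))[1:40]
  res3 <- niche_enrichment(fr, low, n_sample = 100, n_iter = 500, seed = 9)
  expect_equal(res3$empirical_p[1], 1)
  expect_error(niche_enrichment(fr, integer(0)), "empty")
  expect_error(niche_enrichment(fr[1:50, ], 1:5, n_sample = 100), "fewer")
})

test_that("BH adjustment equals the textbook step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
  set.seed(97)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, method = "BH"), bh_stepup(p), tolerance = 1e-15)
  }
})

test_that("condition program tests detect planted shifts on masked spots", {
  set.seed(98)
  n_spots <- 200
  conditions <- rep(c("ctrl", "perturbed"), each = n_spots / 2)
  base <- rnorm(n_spots, 0, 1)
  shifted <- base + ifelse(conditions == "perturbed", 1, 0)
  scores <- list(null_prog = base, shifted_prog = shifted)
  masks <- list(null_prog = rep(TRUE, n_spots), shifted_prog = rep(TRUE, n_spots))
  res <- condition_program_test(scores, conditions, masks)
  expect_gt(res$adjusted_p[res$program == "null_prog"], 0.01)
  expect_lt(res$adjusted_p[res$program == "shifted_prog"], 0.01)
  expect_gt(res$t[res$program == "shifted_prog"], 0)
  # bonferroni is never smaller than BH
  res_b <- condition_program_test(scores, conditions, masks, adjust = "bonferroni")
  expect_true(all(res_b$adjusted_p >= res$adjusted_p - 1e-15))
  # masking away a condition errors
  bad_mask <- list(null_prog = conditions == "ctrl",
                   shifted_prog = rep(TRUE, n_spots))
  expect_error(condition_program_test(scores, conditions, bad_mask), "fewer than 3")
})
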