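square_meta <- function(n_rows, n_cols, section = "sec1") {
  tibble::tibble(
    spot_id = sprintf("s%04d", seq_len(n_rows * n_cols)),
    array_row = rep(seq_len(n_rows), n_cols),
    array_col = rep(seq_len(n_cols), each = n_rows),
    section_id = section
  )
}

test_that("tumor-state clustering recovers well-separated Dirichlet modes", {
  set.seed(100)
  k <- 4; n_per <- 40
  alpha <- diag(30, k) + 1
  fr <- do.call(rbind, lapply(seq_len(k), function(m) {
    t(replicate(n_per, {
      g <- rgamma(k, alpha[m, ]); g / sum(g)
    }))
  }))
  colnames(fr) <- paste0("state", seq_len(k))
  labels <- cluster_tumor_spots(fr, k_states = k)
  truth <- rep(seq_len(k), each = n_per)
  # adjusted Rand via mclust (independent implementation)
  ari <- mclust::adjustedRandIndex(labels, truth)
  expect_gte(ari, 0.9)
  expect_error(cluster_tumor_spots(fr[1:3, ], k_states = 7), "fewer")
  const <- matrix(0.25, 20, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_error(cluster_tumor_spots(const, k_states = 2), "constant|informative")
  expect_identical(cluster_tumor_spots(fr, k_states = 1), rep(1L, nrow(fr)))
})

test_that("cluster labels take the dominant state, honour merges and log ties", {
  fr <- rbind(
    matrix(rep(c(0.6, 0.3, 0.1), each = 5), 5),
    matrix(rep(c(0.1, 0.7, 0.2), each = 5), 5)
  )
  colnames(fr) <- c("AT1-like", "AT2-like", "gastric")
  cl <- rep(1:2, each = 5)
  lab <- label_clusters(cl, fr)
  expect_identical(lab$label, c("AT1-like", "AT2-like"))
  merged <- label_clusters(cl, fr, merge_pairs = list(c("AT1-like", "AT2-like")))
  expect_identical(unique(merged$label), "AT1-like+AT2-like")
  tie <- matrix(rep(c(0.5, 0.5, 0), each = 4), 4)
  colnames(tie) <- colnames(fr)
  expect_message(tlab <- label_clusters(rep(1, 4), tie), "tie")
  expect_identical(tlab$label, "AT1-like")
})

test_that("lesion components equal the flood-fill oracle on random labelings", {
  set.seed(101)
  meta <- square_meta(20, 20)
  for (rep in 1:3) {
    labels <- sample(c("a", "b", "c"), 400, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    lm <- lesion_components(meta, labels, lattice = "square", min_spots = 0)
    oracle <- flood_fill_components(meta, labels, "square")
    # same partition: components must be identical up to relabeling
    expect_equal(length(unique(lm$lesion_id)), length(unique(oracle)))
    expect_true(all(tapply(oracle, lm$lesion_id, function(v) length(unique(v))) == 1))
  }
})

test_that("size filter retains 7-spot components and drops 6-spot components", {
  meta <- square_meta(8, 8)
  labels <- rep("bg", 64)
  idx <- function(r, c) which(meta$array_row == r & meta$array_col == c)
  seven <- c(idx(1, 1), idx(1, 2), idx(1, 3), idx(2, 1), idx(2, 2),
             idx(3, 1), idx(4, 1))
  six <- c(idx(6, 6), idx(6, 7), idx(6, 8), idx(7, 6), idx(7, 7), idx(8, 6))
  labels[seven] <- "tumorA"
  labels[six] <- "tumorB"
  lm <- lesion_components(meta, labels, lattice = "square", min_spots = 6)
  expect_true(all(!is.na(lm$lesion_id[seven])))
  expect_true(all(is.na(lm$lesion_id[six])))
  # diagonal touching blocks are separate under rook adjacency
  labels2 <- rep("bg", 64)
  block1 <- c(idx(1, 1), idx(1, 2), idx(2, 1), idx(2, 2))
  block2 <- c(idx(3, 3), idx(3, 4), idx(4, 3), idx(4, 4))
  labels2[c(block1, block2)] <- "t"
  lm2 <- lesion_components(meta, labels2, lattice = "square", min_spots = 0)
  expect_identical(length(unique(lm2$lesion_id[c(block1, block2)])), 2L)
  # a solid 3x3 block is one lesion of 9
  labels3 <- rep("bg", 64)
  nine <- as.vector(outer(1:3, 1:3, Vectorize(function(r, c) idx(r, c))))
  labels3[nine] <- "t"
  lm3 <- lesion_components(meta, labels3, lattice = "square", min_spots = 0)
  expect_identical(unique(lm3$lesion_size[nine]), 9L)
})

test_that("hex adjacency connects offset rows the Visium way", {
  meta <- tibble::tibble(
    spot_id = paste0("s", 1:4),
    array_row = c(1, 1, 2, 2),
    array_col = c(2, 4, 1, 3),
    section_id = "sec"
  )
  labels <- rep("t", 4)
  lm <- lesion_components(meta, labels, lattice = "hex", min_spots = 0)
  expect_identical(length(unique(lm$lesion_id)), 1L)   # all mutually connected
})

test_that("immune response classification applies the strict 10% rule monotonically", {
  meta <- square_meta(2, 10)
  labels <- rep(c("A", "B"), each = 10)
  lm <- lesion_components(meta, labels, lattice = "square", min_spots = 6)
  make_niche <- function(n_ic) {
    tibble::tibble(spot = meta$spot_id,
                   ic = c(rep(TRUE, n_ic), rep(FALSE, 20 - n_ic)),
                   ifn = FALSE)
  }
  # 1 of 10 spots = 10% exactly -> not responding (strict >)
  r1 <- classify_immune_response(lm, make_niche(1))
  expect_false(r1$immune_response[r1$lesion_label == "A"])
  r2 <- classify_immune_response(lm, make_niche(2))
  expect_true(r2$immune_response[r2$lesion_label == "A"])
  expect_false(r2$immune_response[r2$lesion_label == "B"])
  r0 <- classify_immune_response(lm, make_niche(0))
  expect_false(any(r0$immune_response))
  # monotone: adding niche spots never flips responding -> non-responding
  for (n in 3:10) {
    rn <- classify_immune_response(lm, make_niche(n))
    expect_true(rn$immune_response[rn$lesion_label == "A"])
  }
})

test_that("lesion DE recovers planted shifts with BH control and applies prefilters", {
  set.seed(102)
  n_per <- 100; n_genes <- 300
  lognorm <- matrix(rnorm(2 * n_per * n_genes, 1, 0.7), 2 * n_per, n_genes)
  lognorm <- pmax(lognorm, 0)
  colnames(lognorm) <- sprintf("g%03d", seq_len(n_genes))
  up <- 1:30
  lognorm[1:n_per, up] <- lognorm[1:n_per, up] + 1
  res <- lesion_de(lognorm, group_a = 1:n_per, group_b = (n_per + 1):(2 * n_per))
  called_up <- res$gene[!is.na(res$significant) & res$significant == "up_a"]
  expect_gte(sum(called_up %in% colnames(lognorm)[up]), 27)
  fdr <- 1 - mean(called_up %in% colnames(lognorm)[up])
  expect_lte(fdr, 0.05)

  # detection prefilter: gene present in <10% of spots in both groups is excluded
  sparse <- lognorm
  sparse[, 31] <- 0
  sparse[sample(1:n_per, 8), 31] <- 3          # 8% detection in group A
  sparse[n_per + sample(1:n_per, 5), 31] <- 0.1
  res2 <- lesion_de(sparse, 1:n_per, (n_per + 1):(2 * n_per))
  expect_false("g031" %in% res2$gene)
  # identical groups yield nothing significant
  res3 <- lesion_de(lognorm[c(n_per + 1:50, n_per + 51:100), ],
                    1:50, 51:100)
  expect_true(all(is.na(res3$significant)))
  expect_error(lesion_de(lognorm, integer(0), 1:5), "non-empty")
})

test_that("the niche-bearing lesion is the one flagged responding end-to-end", {
  flags <- vapply(1:10, function(s) {
    sim <- simulate_spot_grid(
      seed = 200 + s,
      lesion_spec = list(
        list(rows = c(4, 8), cols = c(4, 8), state = "stateA", with_niche = TRUE),
        list(rows = c(14, 18), cols = c(14, 18), state = "stateB", with_niche = FALSE)
      )
    )
    lognorm <- nichefactor:::lognorm_matrix(sim$grid$counts)
    ic <- module_score(lognorm, sim$truth$ic_genes, seed = 1)
    ifn <- module_score(lognorm, sim$truth$ifn_genes, seed = 2)
    calls <- call_niches(ic, ifn, gamma_tail_threshold(ic), gamma_tail_threshold(ifn))
    tumor <- sim$truth$lesion_layout$region == "core"
    lm <- lesion_components(
      sim$grid$spot_meta[tumor, ],
      sim$truth$lesion_layout$state[tumor], lattice = "square"
    )
    resp <- classify_immune_response(lm, calls[tumor, ])
    a <- resp$immune_response[resp$lesion_label == "stateA"]
    b <- resp$immune_response[resp$lesion_label == "stateB"]
    isTRUE(a) && isFALSE(b)
  }, logical(1))
  expect_gte(mean(flags), 0.9)
})
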