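# Shared sampler: gamma loading matrix with sparse shape
rgamma_matrix <- function(nr, nc, shape, rate) {
  matrix(rgamma(nr * nc, shape = shape, rate = rate), nr, nc)
}

rdirichlet_one <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate counts from the hierarchical Poisson factorization model
#'
#' Draws gamma-distributed cell loadings (theta) and gene loadings (beta)
#' and Poisson counts with mean theta beta'. Cells of the perturbed
#' condition have their loadings on `shifted_factors` multiplied by
#' `shift_multiplier`, so the same gene programs change usage between
#' conditions. The generated truth is returned for recovery tests.
#'
#' @param n_cells,n_genes,k Dimensions.
#' @param shifted_factors Factor indices shifted in the perturbed condition.
#' @param shift_multiplier Positive usage multiplier (1 = exchangeable null).
#' @param cluster_spec Named list `condition -> integer vector of cluster
#'   sizes`; must total `n_cells`. Default: both conditions, one cluster
#'   each, cells split as evenly as possible.
#' @param loading_shape Gamma shape of theta and beta (sparse loadings).
#' @param mean_library_size Target expected UMIs per control cell; sets the
#'   gamma rates.
#' @param n_samples_per_condition Cells of each condition are split evenly
#'   over this many sample labels.
#' @param seed Integer seed.
#' @return List with `counts` (a `count_matrix`) and `truth` (a `sim_truth`:
#'   true_gene_scores, true_cell_scores, shifted_factors, shift_multiplier).
#' @export
simulate_hpf_counts <- function(n_cells, n_genes, k,
                                shifted_factors = integer(0),
                                shift_multiplier = 1,
                                cluster_spec = NULL,
                                loading_shape = 0.3,
                                mean_library_size = 1500,
                                n_samples_per_condition = 2,
                                seed = 1L) {
  stopifnot(n_cells >= 1, n_genes >= 1, k >= 1, shift_multiplier > 0)
  if (length(shifted_factors) && any(shifted_factors < 1 | shifted_factors > k)) {
    abort("shifted_factors must lie in 1..k")
  }
  if (is.null(cluster_spec)) {
    n_ctrl <- ceiling(n_cells / 2)
    cluster_spec <- list(ctrl = n_ctrl, perturbed = n_cells - n_ctrl)
  }
  sizes <- unlist(cluster_spec)
  if (sum(sizes) != n_cells) abort("cluster_spec sizes must total n_cells")
  if (any(vapply(cluster_spec, sum, numeric(1)) == 0)) {
    abort("every condition needs at least one cell")
  }
  conditions <- rep(names(cluster_spec), times = vapply(cluster_spec, sum, numeric(1)))
  clusters <- unlist(lapply(cluster_spec, function(cs) {
    rep(paste0("cluster", seq_along(cs)), times = cs)
  }))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  # rate so that E[library] = n_genes * k * E[theta] E[beta] = mean_library_size
  rate <- sqrt(n_genes * k * loading_shape^2 / mean_library_size)
  theta <- rgamma_matrix(n_cells, k, loading_shape, rate)
  beta <- rgamma_matrix(n_genes, k, loading_shape, rate)
  perturbed <- conditions != names(cluster_spec)[1]
  if (length(shifted_factors) && shift_multiplier != 1) {
    theta[perturbed, shifted_factors] <-
      theta[perturbed, shifted_factors] * shift_multiplier
  }
  mu <- theta %*% t(beta)
  y <- matrix(rpois(length(mu), mu), n_cells, n_genes)
  colnames(y) <- sprintf("g%04d", seq_len(n_genes))
  rownames(y) <- sprintf("cell%05d", seq_len(n_cells))
  sample_id <- paste0(
    conditions, "_s",
    (ave(seq_len(n_cells), conditions, FUN = seq_along) - 1) %%
      n_samples_per_condition + 1
  )
  meta <- tibble(cell_id = rownames(y), sample_id = sample_id,
                 condition = conditions, lineage = "sim", cluster = clusters)
  dimnames(theta) <- list(rownames(y), paste0("factor_", seq_len(k)))
  dimnames(beta) <- list(colnames(y), paste0("factor_", seq_len(k)))
  truth <- structure(
    list(true_gene_scores = beta, true_cell_scores = theta,
         shifted_factors = shifted_factors, shift_multiplier = shift_multiplier,
         seed = seed),
    class = "sim_truth"
  )
  list(counts = count_matrix(y, meta), truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  parts <- c(
    if (!is.null(x$true_gene_scores)) {
      sprintf("%d genes x %d factors", nrow(x$true_gene_scores),
              ncol(x$true_gene_scores))
    },
    if (!is.null(x$niche_mask_ic)) sprintf("%d spots", length(x$niche_mask_ic)),
    if (!is.null(x$treg_proportion)) sprintf("%d samples", length(x$treg_proportion))
  )
  cat(sprintf("<sim_truth> %s\n", paste(parts, collapse = "; ")))
  invisible(x)
}

#' Simulate a two-species pair sharing orthologous gene programs
#'
#' Species A takes the dimensions, cell loadings and baseline gene loadings
#' of `base_truth`, then anchors every factor with a disjoint block of
#' strongly loaded program genes (the well-separated structure real gene
#' programs show). Species B has its own gene symbols, linked one-to-one to
#' a fraction of species-A genes. The first `n_shared_factors` factors load
#' the same orthologous genes in both species; the remaining factors anchor
#' species-private program blocks.
#'
#' @param base_truth A `sim_truth` from [simulate_hpf_counts()] (species A).
#' @param n_shared_factors Number of leading factors shared across species.
#' @param ortholog_fraction Fraction of genes covered by the one-to-one map.
#' @param n_cells_b Cells simulated for species B.
#' @param genes_per_program Size of each factor's anchor block (shrunk if the
#'   gene universe cannot hold disjoint blocks for all programs).
#' @param program_boost Loading added to anchor genes, in units of the mean
#'   baseline loading.
#' @param seeds Integer pair: (species-B loading seed, count seed).
#' @return List with `counts_a`, `counts_b`, `map` (an `ortholog_map`),
#'   `truth_a`, `truth_b` (the returned `truth_a` carries the
#'   program-structured gene scores actually used for species A's counts).
#' @export
simulate_cross_species_pair <- function(base_truth, n_shared_factors,
                                        ortholog_fraction = 1,
                                        n_cells_b = NULL,
                                        genes_per_program = 25,
                                        program_boost = 20,
                                        seeds = c(1L, 2L)) {
  beta_a <- base_truth$true_gene_scores
  theta_a <- base_truth$true_cell_scores
  k <- ncol(beta_a)
  n_genes <- nrow(beta_a)
  if (n_shared_factors > k) abort("n_shared_factors exceeds k")
  stopifnot(ortholog_fraction > 0, ortholog_fraction <= 1)
  if (is.null(n_cells_b)) n_cells_b <- nrow(theta_a)
  n_private <- k - n_shared_factors
  n_blocks <- k + n_private
  gpp <- min(genes_per_program, floor(n_genes / n_blocks))
  if (gpp < 1) abort("gene universe too small for disjoint program blocks")
  boost <- program_boost * mean(beta_a)
  block_genes <- function(b) ((b - 1) * gpp + 1):(b * gpp)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seeds[1])

  # species A: factor f anchored by block f
  for (f in seq_len(k)) beta_a[block_genes(f), f] <- beta_a[block_genes(f), f] + boost

  genes_b <- sprintf("B%04d", seq_len(n_genes))
  n_mapped <- round(ortholog_fraction * n_genes)
  mapped_idx <- sort(sample.int(n_genes, n_mapped))
  map <- ortholog_map(tibble(
    symbol_a = rownames(beta_a)[mapped_idx],
    symbol_b = genes_b[mapped_idx]
  ))

  shape <- 0.3
  rate_b <- shape / mean(base_truth$true_gene_scores)
  beta_b <- rgamma_matrix(n_genes, k, shape, rate_b)
  rownames(beta_b) <- genes_b
  colnames(beta_b) <- paste0("factor_", seq_len(k))
  if (n_shared_factors > 0) {
    # shared programs: orthologous genes carry species-A loadings
    beta_b[mapped_idx, seq_len(n_shared_factors)] <-
      beta_a[mapped_idx, seq_len(n_shared_factors)]
  }
  if (n_private > 0) {
    for (f in seq_len(n_private)) {
      # species-private programs anchor blocks disjoint from species A's
      idx <- block_genes(k + f)
      beta_b[idx, n_shared_factors + f] <- beta_b[idx, n_shared_factors + f] + boost
    }
  }
  theta_b <- rgamma_matrix(n_cells_b, k, shape, shape / mean(theta_a))
  rownames(theta_b) <- sprintf("bcell%05d", seq_len(n_cells_b))
  colnames(theta_b) <- colnames(beta_b)

  set.seed(seeds[2])
  mu_b <- theta_b %*% t(beta_b)
  y_b <- matrix(rpois(length(mu_b), mu_b), nrow(mu_b), ncol(mu_b),
                dimnames = list(rownames(theta_b), genes_b))
  counts_b <- count_matrix(y_b, tibble(cell_id = rownames(y_b),
                                       condition = "ctrl", lineage = "sim"))
  mu_a <- theta_a %*% t(beta_a)
  y_a <- matrix(rpois(length(mu_a), mu_a), nrow(mu_a), ncol(mu_a),
                dimnames = dimnames(mu_a))
  counts_a <- count_matrix(y_a)
  truth_b <- structure(
    list(true_gene_scores = beta_b, true_cell_scores = theta_b,
         shared_factors = seq_len(n_shared_factors), seed = seeds[1]),
    class = "sim_truth"
  )
  truth_a <- base_truth
  truth_a$true_gene_scores <- beta_a
  truth_a$shared_factors <- seq_len(n_shared_factors)
  list(counts_a = counts_a, counts_b = counts_b, map = map,
       truth_a = truth_a, truth_b = truth_b,
       shared_factors = seq_len(n_shared_factors))
}

#' Simulate a sample cohort with a T_reg-proportion gradient
#'
#' Generates per-sample T_reg proportions and cell loadings whose
#' log2 mean usage of `responsive_factors` correlates with the log2 T_reg
#' proportion at approximately `rho_target` (a Gaussian-copula construction:
#' the population correlation of the two log quantities equals the target).
#'
#' @param n_samples Samples (>= 5).
#' @param responsive_factors Factor indices tied to the gradient.
#' @param rho_target Target Spearman sign/strength in [-1, 1].
#' @param n_cells_per_sample Cells per sample.
#' @param n_genes,k Count-matrix dimensions.
#' @param effect_sd Spread (log2 units) of the sample-level usage signal.
#' @param seed Integer seed.
#' @return List with `counts` (a `count_matrix` with sample labels),
#'   `treg_proportion` (named per-sample vector) and `truth`.
#' @export
simulate_treg_cohort <- function(n_samples, responsive_factors,
                                 rho_target, n_cells_per_sample = 100,
                                 n_genes = 100, k = 5, effect_sd = 1,
                                 seed = 1L) {
  if (n_samples < 5) abort("n_samples must be at least 5 (correlation degenerates)")
  if (abs(rho_target) > 1) abort("|rho_target| must not exceed 1")
  stopifnot(all(responsive_factors >= 1 & responsive_factors <= k))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  treg <- plogis(rnorm(n_samples, mean = -2, sd = 1))   # proportions in (0,1)
  z_t <- as.vector(scale(log2(treg)))
  signal <- rho_target * z_t + sqrt(1 - rho_target^2) * rnorm(n_samples)
  sample_effect <- 2^(effect_sd * signal)

  n_cells <- n_samples * n_cells_per_sample
  shape <- 0.3
  rate <- sqrt(n_genes * k * shape^2 / 1500)
  theta <- rgamma_matrix(n_cells, k, shape, rate)
  sample_id <- rep(sprintf("sample%02d", seq_len(n_samples)),
                   each = n_cells_per_sample)
  theta[, responsive_factors] <- theta[, responsive_factors] *
    rep(sample_effect, each = n_cells_per_sample)
  beta <- rgamma_matrix(n_genes, k, shape, rate)
  mu <- theta %*% t(beta)
  y <- matrix(rpois(length(mu), mu), n_cells, n_genes,
              dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                              sprintf("g%04d", seq_len(n_genes))))
  meta <- tibble(cell_id = rownames(y), sample_id = sample_id,
                 condition = "ctrl", lineage = "sim", cluster = "cluster1")
  dimnames(theta) <- list(rownames(y), paste0("factor_", seq_len(k)))
  dimnames(beta) <- list(colnames(y), paste0("factor_", seq_len(k)))
  names(treg) <- sprintf("sample%02d", seq_len(n_samples))
  truth <- structure(
    list(true_gene_scores = beta, true_cell_scores = theta,
         responsive_factors = responsive_factors, rho_target = rho_target,
         treg_proportion = treg, seed = seed),
    class = "sim_truth"
  )
  list(counts = count_matrix(y, meta), treg_proportion = treg, truth = truth)
}

#' Simulate a spatial spot lattice with lesions and signaling niches
#'
#' Lays out a square or hex lattice, plants rectangular tumor lesions with
#' per-lesion transcriptional states, draws per-spot cell-type fractions from
#' region-dependent Dirichlet distributions (lesion core is tumor-heavy, the
#' margin immune-heavy), and elevates the inflammatory-cytokine program genes
#' in lesion cores and the interferon program genes in lesion margins of
#' niche-bearing lesions.
#'
#' @param n_rows,n_cols Grid dimensions (>= 3 each).
#' @param lattice `"square"` or `"hex"` (hex uses Visium-style offset
#'   columns: column parity matches row parity).
#' @param cell_types Cell-type names; the first is the tumor type.
#' @param lesion_spec List of lesions, each a list with `rows` (range),
#'   `cols` (range), `state` (label), `with_niche` (logical).
#' @param niche_spec List with `ic_effect`, `ifn_effect` (log-expression
#'   elevation of program genes in core/margin spots of niche-bearing
#'   lesions), `n_program_genes`.
#' @param n_genes Total genes.
#' @param mean_library_size Expected UMIs per spot.
#' @param condition Condition label stored on every spot.
#' @param section_id Section label.
#' @param seed Integer seed.
#' @return List with `grid` (a `spot_grid` with fractions and summed_expr)
#'   and `truth` (`sim_truth` with `niche_mask_ic`, `niche_mask_ifn`,
#'   `lesion_layout`, `presence_truth`, `ic_genes`, `ifn_genes`).
#' @export
simulate_spot_grid <- function(n_rows = 24, n_cols = 24,
                               lattice = c("square", "hex"),
                               cell_types = c("tumor", "endothelial",
                                              "fibroblast", "myeloid", "tcell"),
                               lesion_spec = NULL,
                               niche_spec = list(ic_effect = 1.0,
                                                 ifn_effect = 1.0,
                                                 n_program_genes = 30),
                               n_genes = 200,
                               mean_library_size = 5000,
                               condition = "perturbed",
                               section_id = "section1",
                               seed = 1L) {
  lattice <- match.arg(lattice)
  if (n_rows < 3 || n_cols < 3) abort("grid must be at least 3x3")
  if (is.null(lesion_spec)) {
    lesion_spec <- list(
      list(rows = c(4, 8), cols = c(4, 8), state = "stateA", with_niche = TRUE),
      list(rows = c(14, 18), cols = c(14, 18), state = "stateB", with_niche = TRUE)
    )
  }
  niche_spec <- utils::modifyList(
    list(ic_effect = 1.0, ifn_effect = 1.0, n_program_genes = 30), niche_spec
  )
  if (niche_spec$ic_effect < 0 || niche_spec$ifn_effect < 0) {
    abort("niche effect sizes must be non-negative")
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  coords <- expand.grid(array_row = seq_len(n_rows), array_col = seq_len(n_cols))
  if (lattice == "hex") {
    # Visium-style offset lattice: column parity matches row parity
    coords$array_col <- 2 * coords$array_col - (coords$array_row %% 2)
  }
  n_spots <- nrow(coords)
  region <- rep("normal", n_spots)
  lesion_state <- rep(NA_character_, n_spots)
  lesion_id <- rep(NA_integer_, n_spots)
  core_niche <- margin_niche <- rep(FALSE, n_spots)
  grid_col <- ceiling(coords$array_col / if (lattice == "hex") 2 else 1)
  for (li in seq_along(lesion_spec)) {
    ls <- lesion_spec[[li]]
    if (max(ls$rows) > n_rows || max(ls$cols) > n_cols ||
        min(ls$rows) < 1 || min(ls$cols) < 1) {
      abort("lesion outside the grid")
    }
    core <- coords$array_row >= ls$rows[1] & coords$array_row <= ls$rows[2] &
      grid_col >= ls$cols[1] & grid_col <= ls$cols[2]
    margin <- coords$array_row >= ls$rows[1] - 1 & coords$array_row <= ls$rows[2] + 1 &
      grid_col >= ls$cols[1] - 1 & grid_col <= ls$cols[2] + 1 & !core
    region[core] <- "core"
    region[margin & region == "normal"] <- "margin"
    lesion_state[core] <- ls$state
    lesion_id[core] <- li
    if (isTRUE(ls$with_niche)) {
      core_niche <- core_niche | core
      margin_niche <- margin_niche | (margin & region != "core")
    }
  }

  # region-dependent Dirichlet fractions; first type is the tumor type
  n_types <- length(cell_types)
  alpha_for <- function(reg) {
    base <- rep(2, n_types)
    if (reg == "core") base[1] <- 30
    if (reg == "margin") { base[1] <- 4; base[n_types] <- 10 }
    if (reg == "normal") base[1] <- 0.2
    base
  }
  fractions <- t(vapply(region, function(r) rdirichlet_one(alpha_for(r)),
                        numeric(n_types)))
  colnames(fractions) <- cell_types
  presence_truth <- t(vapply(region, function(r) {
    pres <- rep(TRUE, n_types)
    pres[1] <- r == "core"   # tumor present only in lesion cores
    pres
  }, logical(n_types)))
  colnames(presence_truth) <- cell_types

  npg <- niche_spec$n_program_genes
  if (n_genes < 2 * npg + 10) abort("n_genes too small for the program layout")
  genes <- sprintf("g%04d", seq_len(n_genes))
  ic_genes <- genes[seq_len(npg)]
  ifn_genes <- genes[npg + seq_len(npg)]
  log_base <- rnorm(n_genes, mean = 0, sd = 0.5)
  eff <- matrix(0, n_spots, n_genes)
  eff[core_niche, seq_len(npg)] <- niche_spec$ic_effect
  eff[margin_niche, npg + seq_len(npg)] <- niche_spec$ifn_effect
  rate <- exp(sweep(eff, 2, log_base, "+"))
  rate <- rate / rowSums(rate) * mean_library_size
  counts <- matrix(rpois(length(rate), rate), n_spots, n_genes,
                   dimnames = list(sprintf("spot%05d", seq_len(n_spots)), genes))

  meta <- tibble(
    spot_id = rownames(counts),
    array_row = coords$array_row, array_col = coords$array_col,
    section_id = section_id, condition = condition,
    region = region, lesion_id = lesion_id, lesion_state = lesion_state
  )
  summed_expr <- fractions * rowSums(counts)
  grid <- spot_grid(counts, meta, fractions = fractions,
                    summed_expr = summed_expr)
  truth <- structure(
    list(niche_mask_ic = setNames(core_niche, rownames(counts)),
         niche_mask_ifn = setNames(margin_niche, rownames(counts)),
         lesion_layout = tibble(spot_id = rownames(counts),
                                region = region, lesion_id = lesion_id,
                                state = lesion_state),
         presence_truth = presence_truth,
         ic_genes = ic_genes, ifn_genes = ifn_genes, seed = seed),
    class = "sim_truth"
  )
  list(grid = grid, truth = truth)
}
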