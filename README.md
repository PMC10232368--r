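# nichefactor

Tools for measuring how a perturbation — prototypically, acute depletion of
regulatory T (T_reg) cells in a tumor-bearing lung — propagates through the
accessory cell types of a tissue. The package is aimed at computational
biologists working with single-cell RNA-seq of perturbed tissues and
spot-based spatial transcriptomics with an external deconvolution step.

At its core are four connected pieces of machinery:

* **Hierarchical Poisson factorization (HPF).** Counts are modeled as
  y<sub>ui</sub> ~ Poisson(Σ<sub>k</sub> θ<sub>uk</sub> β<sub>ik</sub>) with
  gamma priors θ<sub>uk</sub> ~ Gamma(a, ξ<sub>u</sub>),
  β<sub>ik</sub> ~ Gamma(c, η<sub>i</sub>) and gamma hyper-priors on the
  capacities ξ, η. `fit_hpf()` runs coordinate-ascent variational inference
  (C++ inner loop) and returns posterior-mean gene scores and cell scores —
  the gene programs and their per-cell usage.
* **Program stability and differential usage.** Restart and
  factor-count robustness via minimum-cost Hungarian matching under cost
  1 − Pearson (`restart_robustness()`, `k_robustness()`,
  `match_factors()`); cluster × condition usage tables with Mann–Whitney
  tests and p < 0.01 selection of perturbation-responsive factors
  (`usage_table()`, `select_responsive_factors()`).
* **Cross-species conservation.** One-to-one ortholog restriction,
  mean + 2 SD gene-to-factor assignment, Jaccard similarity with per-factor
  z-scores and lineage-specific call thresholds (0.06/0.07), and Spearman
  correlation of log2 program usage with log2 T_reg proportion across
  samples (`jaccard_homology()`, `treg_usage_correlation()`).
* **Spatial niches and lesions.** Bin-matched module scores (24 bins, 100
  controls), gamma-tail niche thresholds (MLE fit to score + 1, upper-tail
  0.01), gamma/Gaussian mixture binarization of deconvolved cell-type
  fractions (70% posterior, floors 0.001 and 50), 100-spot × 10,000-draw
  resampling enrichment with BH adjustment, tumor-state clustering
  (correlation distance, average linkage, k = 7), connected-component
  lesion areas (> 6 spots) with the > 10% immune-response rule, and
  Wilcoxon spot-level differential expression.

Every stage has a synthetic-data generator with planted ground truth
(`simulate_hpf_counts()`, `simulate_cross_species_pair()`,
`simulate_treg_cohort()`, `simulate_spot_grid()`), so the whole pipeline is
testable without any external dataset.

## Worked example

Simulate counts whose perturbed condition triples its usage of one planted
program, fit the model, check restart stability, and ask which factor
responded:

```r
library(nichefactor)

sim <- simulate_hpf_counts(500, 300, k = 4, shifted_factors = 2,
                           shift_multiplier = 3, seed = 42)
model <- fit_hpf(sim$counts, hpf_hyperparams(k = 4, seed = 1))
glance(model)
#> # A tibble: 1 × 6
#>       k n_genes n_cells n_iter     elbo converged
#> 1     4     300     500     49 1668876. TRUE

rr <- restart_robustness(sim$counts, hpf_hyperparams(k = 4, seed = 1),
                         n_restarts = 4)
rr
#> <restart_robustness> 6 restart pairs; pairwise medians 1.000-1.000

ut <- usage_table(model, sim$counts$cell_meta$cluster,
                  sim$counts$cell_meta$condition)
select_responsive_factors(ut, rr, alpha = 0.01)
#> [1] 4
dplyr::filter(ut$tests, factor == 4)
#>   factor cluster      U         p mean_ctrl mean_perturbed
#> 1      4 cluster1 24528 0.0000317     0.798           2.07
```

Fitted factor indices are arbitrary; Hungarian matching against the planted
truth shows fitted factor 4 is the planted (shifted) factor 2, recovered at
gene-score correlation 1.000:

```r
truth <- factor_model_from_scores(sim$truth$true_gene_scores,
                                  sim$truth$true_cell_scores)
match_factors(model, truth, on = "gene")$pairs
#>   factor_a factor_b corr_gene  corr
#> 1        1        3     0.999 0.999
#> 2        2        4     1.000 1.000
#> 3        3        1     1.000 1.000
#> 4        4        2     1.000 1.000
```

The selected factor's mean usage in the perturbed condition (2.07) is about
three times the control mean (0.80) — the planted multiplier — and the
Mann–Whitney p-value (3.2e-5) clears the 0.01 selection threshold.

The spatial side works the same way: `simulate_spot_grid()` plants lesions
and core/margin signaling niches, `module_score()` +
`gamma_tail_threshold()` + `call_niches()` localize them, and
`lesion_components()` + `classify_immune_response()` decide which lesions
responded. See the vignette (`vignettes/gene-programs-and-niches.Rmd`) for
the full model and every numerical choice.

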