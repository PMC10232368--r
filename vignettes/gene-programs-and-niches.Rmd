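---
title: "Gene programs and spatial signaling niches: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene programs and spatial signaling niches: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichefactor)
```

## The scientific problem

When regulatory T (T_reg) cells are acutely depleted from a tumor-bearing
tissue, the earliest transcriptional consequences appear not in effector T
cells but in the accessory compartments — endothelium, fibroblasts, myeloid
cells. `nichefactor` implements the computational machinery for quantifying
that "connectivity": which coordinated gene programs change usage when the
perturbation hits, whether the same programs exist in another species, and
where in the tissue the programs fire.

The pipeline has four layers, each exercisable on synthetic data with
planted ground truth:

1. **Factorization.** Hierarchical Poisson factorization (HPF) of cell × gene
   UMI counts into non-negative gene scores and cell scores.
2. **Program analysis.** Differential factor usage between two conditions,
   factor-associated gene programs on cell subsets, and restart/k robustness.
3. **Cross-species conservation.** Ortholog-restricted gene assignment,
   Jaccard homology with z-scoring, and cohort-level correlation of program
   usage with T_reg abundance.
4. **Spatial localization.** Module scores of shared programs per spot,
   gamma-tail signaling-niche calls, mixture-model presence binarization of
   deconvolved cell-type fractions, resampling enrichment, lesion
   segmentation and spot-level differential expression.

## The factorization model

HPF is a fully Bayesian non-negative factorization built for sparse count
data. With cells $u$, genes $i$ and $K$ factors:

$$
\xi_u \sim \mathrm{Gamma}(a', a'/b'), \qquad
\theta_{uk} \sim \mathrm{Gamma}(a, \xi_u),
$$
$$
\eta_i \sim \mathrm{Gamma}(c', c'/d'), \qquad
\beta_{ik} \sim \mathrm{Gamma}(c, \eta_i), \qquad
y_{ui} \sim \mathrm{Poisson}\Big(\sum_k \theta_{uk}\beta_{ik}\Big).
$$

`fit_hpf()` runs mean-field coordinate-ascent variational inference (CAVI)
with gamma variational factors and multinomial auxiliary responsibilities
over the nonzero counts. The evidence lower bound is evaluated once per
sweep with the responsibilities optimized out (log-sum-exp form), which
makes the trace provably non-decreasing; the test suite asserts this at a
relative tolerance of 1e-8. Convergence is declared when the relative ELBO
change drops below `tol` (default 1e-5, at most 500 sweeps). The sweep
itself is implemented in C++ (RcppArmadillo), as the per-iteration work is a
dense pass over all nonzero counts.

**Hyperparameter defaults.** Shapes $a = c = 0.3$ encode sparse loadings —
the convention for single-cell counts, where most genes participate in few
programs. $a' = c' = 1$; the rate hyper-priors $b', d'$ are set from the
data so that the prior mean of $\theta\beta^\top$ matches the observed mean
count (both sides get scale $s = \sqrt{\bar y / K}$). All are overridable
through `hpf_hyperparams()`. Gene and cell scores are the posterior means of
$\beta$ and $\theta$ with no extra hierarchical rescaling; every downstream
step that compares factors (Jaccard assignment, normalized loadings) is
invariant to monotone rescaling, which insulates the pipeline from this
choice.

**Robustness.** `restart_robustness()` refits with distinct seeds and
Hungarian-matches every pair of fits under cost $1 - r$ (Pearson, gene
scores by default — they are condition-independent); `k_robustness()`
matches refits at perturbed factor counts to a baseline. The assignment
solver is an in-package $O(n^3)$ shortest-augmenting-path implementation,
verified in the tests against brute-force enumeration of all pairings for
$k \le 6$. `select_k_topmass()` implements the grid rule used for the human
lineages: choose the largest $k$ at which, on average, ~90% of a cell's
score mass sits in its top 7 factors. The meaning of "variance explained by
the top factors" is not uniquely defined for this model family; the
top-mass reading is this package's documented interpretation, and the
diagnostic is exposed (`topmass_fraction()`) so alternatives can be
compared.

## Differential usage and gene programs

`usage_table()` averages each factor's cell scores per cluster and
condition, min-max normalizes each factor's row of means to [0, 1] for
display, and tests each factor in each cluster with a two-sided
Mann–Whitney U. Selection (`select_responsive_factors()`) requires raw
p < 0.01 in at least one cluster, the perturbed-up direction, and restart
stability (median matched correlation ≥ 0.8). No multiplicity correction is
applied on the factor × cluster grid — the raw threshold is the selection
rule, and the calibration tests verify the per-factor type-I rate matches
the nominal alpha under an exchangeable null.

The Mann–Whitney implementation enumerates all group assignments exactly
for group sizes up to 8 (valid under ties) and otherwise uses the normal
approximation with tie and continuity correction; both paths are checked
against independent oracles (enumeration; `stats::wilcox.test`).

`factor_gene_program()` Pearson-correlates gene expression with a factor's
cell scores on an isolated cell subset and keeps the top 200 genes.
Correlations are computed on raw log-normalized values, not smoothed ones —
on this kind of data the two give very similar rankings, and smoothing adds
parameters without changing the conclusions the tests check. Subsets are
caller-supplied: which subpopulations to pool is a data-specific judgement,
not built-in knowledge.

## Cross-species conservation

Both species' models are restricted to one-to-one orthologs expressed in
both (`restrict_to_orthologs()`); a gene is *assigned* to a factor when its
gene score exceeds the factor mean by two standard deviations
(`assign_genes()`, population SD — at gene-universe sizes the distinction
from the sample SD is negligible). `jaccard_homology()` computes
$J = |A \cap B| / |A \cup B|$ for every factor pair, z-scores each
species-A factor's row across species-B factors, and calls pairs with $J$
above the lineage threshold (0.06 endothelial, 0.07 fibroblast/myeloid),
keeping at most three calls per species-A factor. The raw-J rule is
primary and z is a reported diagnostic: a z cutoff alone misbehaves when a
factor has no true homolog, and the z of a perfect one-hot match is bounded
by $(k-1)/\sqrt{k}$, so it cannot exceed 2 in narrow factorizations.

Factor groups (e.g. summing several factors that split one biological
program across samples) are config-level lists, and outlier-sample
exclusion is always an explicit argument, never automatic.
`treg_usage_correlation()` computes per-sample mean summed usage and
Spearman-correlates $\log_2$ usage against $\log_2$ T_reg proportion,
excluding samples below a per-lineage cell floor (5 for endothelial and
fibroblast, 20 for myeloid presets).

## Spatial localization

**Module scores.** `module_score()` bins all genes into 24 equal-frequency
bins by mean log-normalized expression and samples 100 controls per program
gene from its bin; the score is mean program minus mean control expression
per spot. Equal-frequency binning is this package's choice — the binning
construction is not otherwise pinned down — and bins smaller than the
control count fall back to sampling with replacement, logged.

**Niche calls.** Because most spots carry no program signal, the score
background is modeled by a gamma distribution fitted by maximum likelihood
to score + 1 (pseudocount), pooled across sections; the niche threshold is
the fitted 0.99 quantile minus the pseudocount. The gamma MLE is a Newton
iteration on the shape (tolerance 1e-10, method-of-moments start), verified
against `MASS::fitdistr` in the tests. IC and IFN calls are independent and
non-exclusive. Pooling both conditions' sections into one fit is the
default; per-condition fitting is available by configuration.

**Presence binarization.** Per cell type and section, a two-component gamma
mixture (in-package EM, weighted gamma MLE M-steps) is fitted to RNA
fractions and a two-component Gaussian mixture (`mclust`) to summed
deconvolved expression; the threshold is the minimum value among spots with
> 70% posterior probability of the signal component (the second-highest
mean when three components are configured, the extra component absorbing a
heavy intermediate background). Thresholds below 0.001 (fraction) or 50
(expression) are raised to those floors, the median across sections is
taken, and a spot is "present" only if it passes both cuts. Degenerate
inputs (constant vectors, one-component data) are flagged, not guessed at.

**Enrichment.** `niche_enrichment()` builds an empirical null from 10,000
draws of 100 spots (without replacement within a draw, independent across
draws), reports the fraction of null means above the niche mean as the
empirical p (BH-adjusted across cell types), and the log2 ratio of niche
mean to grand empirical mean as the effect size. The plain
fraction-of-iterations p can be exactly 0; a (B+1)-corrected variant is
available by configuration and off by default. Both BH and Bonferroni are
available for the module-score condition tests (`condition_program_test()`),
since either may be wanted depending on how conservative the program ×
cell-type grid should be; BH is the default.

**Lesions.** Tumor spots (by presence mask) are clustered on z-scored
tumor-state fractions — restriction first, z-scoring second, with the
alternative order exposed — using average-linkage hierarchical clustering
under Pearson correlation distance, cut at 7 groups. Clusters are labeled
by their dominant state (ties break by column order, logged; configured
label pairs can merge). Lesion areas are connected components of
same-labeled tumor spots — rook adjacency on square lattices; on hex
(Visium-style offset) lattices the six neighbors of (r, c) are
(r, c ± 2) and (r ± 1, c ± 1) — and only components strictly larger than
six spots are kept. A lesion "responds" when strictly more than 10% of its
spots sit in an IC or IFN niche. Spot-level differential expression between
responding and non-responding lesions uses the Wilcoxon rank-sum test on
genes detected in ≥ 10% of either group with mean difference > 0.25,
BH-adjusted, reporting significance at adjusted p < 0.01 and |lfc| > 0.5.
All inequalities quoted here are strict where the underlying rule says
"greater than".

## What the synthetic generators emulate — and what they do not

`simulate_hpf_counts()` draws loadings from the same gamma–Poisson process
the factorization assumes (shape 0.3; rates set to hit a mean library size
of 1,500 UMIs over the simulated gene panel — a realistic depth for
droplet data) and multiplies the perturbed condition's cell loadings on the
shifted factors, so the same gene program changes usage, not identity.
`simulate_cross_species_pair()` anchors every factor with a disjoint block
of 25 strongly loaded program genes — the well-separated structure real
gene programs show — and copies the shared factors' loadings across the
ortholog map. `simulate_treg_cohort()` uses a Gaussian-copula construction
so the population correlation between log2 usage and log2 T_reg proportion
equals the target exactly; cell-level sampling noise attenuates the
recovered value slightly, which the recovery tolerance absorbs.
`simulate_spot_grid()` plants rectangular lesions on a 24 × 24 lattice
(two 5 × 5 lesions by default, so cores are ~9% of spots and margins ~8%),
draws spot fractions from region-dependent Dirichlet distributions, and
elevates IC program genes by 1.0 log-units in niche-bearing cores and IFN
genes in margins.

Deliberately not simulated: ambient RNA, doublets, batch effects, segmented
histology images, and the deconvolution inference itself (fractions are
generated directly, as the pipeline consumes them from an external tool).
Passing tests therefore demonstrate that the machinery recovers structure
under the model's own assumptions plus Poisson noise; they do not
demonstrate robustness to the technical artifacts real tissue adds.

## Numerical choices and limitations

* Fits, scores and resampling are bit-reproducible given (parameters, seed);
  every sampler saves and restores the global RNG state.
* The CAVI initialization jitters the variational shapes and rates
  uniformly in ±50% around their prior-implied values; symmetry breaking,
  not informativeness, is the goal.
* Problem sizes in the tests (500 × 300 counts at k = 4; 20 recovery seeds;
  10 restarts; 50-seed homology and lesion sweeps; 100-replicate cohort
  recovery) were chosen as the smallest instances at which the planted
  structure is comfortably identifiable, so the checks measure correctness
  rather than sample-size luck.
* Library-size log-normalization is used for spots; a variance-stabilizing
  transform is a reasonable alternative and conclusions' sensitivity to the
  choice is untested here.
* The marker-merging procedure measures "closest neighbor" by Euclidean
  distance between mean log-normalized profiles over the current gene set;
  each merge strictly reduces the label count, so termination is guaranteed,
  and a collapse to a single label is reported, not silent.
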