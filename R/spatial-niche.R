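#' Genes shared by the three lineages' niche factors
#'
#' The signaling-niche programs (inflammatory-cytokine and interferon) are
#' defined as the triple intersection of the gene sets assigned to the
#' corresponding factor in each of the endothelial, fibroblast and myeloid
#' factorizations.
#'
#' @param assignment_list List of three character vectors (one assigned gene
#'   set per lineage).
#' @return Character vector; empty with a warning if no gene survives.
#' @export
shared_niche_genes <- function(assignment_list) {
  stopifnot(length(assignment_list) == 3)
  out <- Reduce(intersect, assignment_list)
  if (!length(out)) warn("no gene shared by all three lineages")
  out
}

#' Bin-matched module score of a gene set per spot
#'
#' All genes are split into `n_bins` equal-frequency bins by mean
#' log-normalized expression across spots; for each program gene, `n_ctrl`
#' control genes are drawn from its bin, and the score is the mean program
#' expression minus the mean control expression, per spot.
#'
#' @param lognorm Spots x genes log-normalized matrix.
#' @param gene_set Program genes (subset of colnames).
#' @param n_bins Expression bins.
#' @param n_ctrl Controls per program gene.
#' @param seed Seed for control sampling.
#' @return A `module_score`: per-spot numeric `score` plus the control
#'   bookkeeping.
#' @export
module_score <- function(lognorm, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  if (!length(gene_set)) abort("gene_set is empty")
  missing <- setdiff(gene_set, colnames(lognorm))
  if (length(missing)) {
    abort(sprintf("gene_set contains %d gene(s) absent from the matrix",
                  length(missing)))
  }
  if (ncol(lognorm) < n_bins) abort("need at least n_bins genes overall")
  gene_means <- colMeans(lognorm)
  # equal-frequency bins; ties broken by rank so bins stay balanced
  bins <- ggplot2::cut_number(rank(gene_means, ties.method = "first"),
                              n = n_bins, labels = FALSE)
  names(bins) <- colnames(lognorm)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  ctrl_genes <- character(0)
  with_replacement <- FALSE
  for (g in gene_set) {
    pool <- names(bins)[bins == bins[g]]
    if (length(pool) < n_ctrl) with_replacement <- TRUE
    ctrl_genes <- c(ctrl_genes,
                    sample(pool, n_ctrl, replace = length(pool) < n_ctrl))
  }
  if (with_replacement) {
    inform("control bin smaller than n_ctrl: sampled with replacement")
  }
  score <- rowMeans(lognorm[, gene_set, drop = FALSE]) -
    rowMeans(lognorm[, ctrl_genes, drop = FALSE])
  structure(
    list(score = score, gene_set = gene_set, n_bins = n_bins,
         n_ctrl = n_ctrl, seed = seed),
    class = "module_score"
  )
}

#' @export
print.module_score <- function(x, ...) {
  cat(sprintf("<module_score> %d spots; %d program genes; range [%.3f, %.3f]\n",
              length(x$score), length(x$gene_set), min(x$score), max(x$score)))
  invisible(x)
}

# Gamma MLE by Newton iteration on the shape with method-of-moments start.
gamma_mle <- function(x, tol = 1e-10, max_iter = 100, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  w <- weights / sum(weights)
  m <- sum(w * x)
  lm <- sum(w * log(x))
  s <- log(m) - lm
  if (s <= 0) abort("degenerate sample: gamma MLE undefined")
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # MoM-quality start
  for (i in seq_len(max_iter)) {
    step <- (log(shape) - digamma(shape) - s) / (1 / shape - trigamma(shape))
    new_shape <- shape - step
    if (new_shape <= 0) new_shape <- shape / 2
    if (abs(new_shape - shape) < tol * shape) { shape <- new_shape; break }
    shape <- new_shape
  }
  list(shape = shape, rate = shape / m)
}

#' Gamma-tail threshold for niche assignment
#'
#' Fits a gamma distribution by maximum likelihood to the module scores plus
#' a pseudocount, and returns the score at the chosen upper-tail probability
#' (the fitted quantile minus the pseudocount). Spots above the cut are
#' considered to carry genuine program signal rather than background.
#'
#' @param scores Per-spot module scores (a `module_score` or numeric vector),
#'   pooled across all analyzed sections.
#' @param pseudocount Shift making scores positive before the fit.
#' @param tail Upper-tail probability defining the cut.
#' @return List with `shape`, `rate`, `cut` and `fit_diagnostic` (a tibble of
#'   histogram-overlay data: midpoints, empirical and fitted density).
#' @export
gamma_tail_threshold <- function(scores, pseudocount = 1, tail = 0.01) {
  if (inherits(scores, "module_score")) scores <- scores$score
  if (length(scores) < 50) abort("need at least 50 spots for a stable fit")
  shifted <- scores + pseudocount
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0)
    abort(sprintf("non-positive shifted score at spot(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  if (sd(shifted) == 0) abort("constant scores: gamma fit undefined")
  fit <- gamma_mle(shifted)
  cut <- qgamma(1 - tail, shape = fit$shape, rate = fit$rate) - pseudocount
  h <- graphics::hist(shifted, breaks = 30, plot = FALSE)
  diagnostic <- tibble(
    mid = h$mids, empirical = h$density,
    fitted = dgamma(h$mids, shape = fit$shape, rate = fit$rate)
  )
  list(shape = fit$shape, rate = fit$rate, cut = cut, tail = tail,
       pseudocount = pseudocount, fit_diagnostic = diagnostic)
}

#' Call signaling niches from thresholded module scores
#'
#' Thresholds the inflammatory-cytokine and interferon module scores
#' independently; a spot may belong to both niches.
#'
#' @param ic_score,ifn_score `module_score`s (or numeric vectors) over the
#'   same spots.
#' @param ic_threshold,ifn_threshold [gamma_tail_threshold()] results (or
#'   bare cut values).
#' @return A `niche_call` tibble: spot index, `ic`, `ifn` logicals.
#' @export
call_niches <- function(ic_score, ifn_score, ic_threshold, ifn_threshold) {
  get_scores <- function(s) if (inherits(s, "module_score")) s$score else s
  get_cut <- function(t) if (is.list(t)) t$cut else t
  ic <- get_scores(ic_score); ifn <- get_scores(ifn_score)
  if (length(ic) != length(ifn)) abort("scores must cover identical spots")
  out <- tibble(
    spot = if (!is.null(names(ic))) names(ic) else as.character(seq_along(ic)),
    ic = ic > get_cut(ic_threshold),
    ifn = ifn > get_cut(ifn_threshold)
  )
  class(out) <- c("niche_call", class(out))
  out
}

# ---- mixture models for presence binarization ------------------------------

# Two/three component gamma mixture by EM with weighted gamma MLE M-steps.
# Falls back to a method-of-moments split when EM fails to converge.
gamma_mixture_em <- function(x, n_components = 2, max_iter = 500, tol = 1e-8) {
  stopifnot(all(x > 0))
  comp0 <- ceiling(rank(x, ties.method = "first") / length(x) * n_components)
  fit_comp <- function(xs, ws) {
    out <- tryCatch(gamma_mle(xs, weights = ws), error = function(e) NULL)
    if (is.null(out)) {
      m <- sum(ws * xs) / sum(ws)
      v <- sum(ws * (xs - m)^2) / sum(ws)
      out <- list(shape = m^2 / max(v, 1e-12), rate = m / max(v, 1e-12))
    }
    out
  }
  params <- lapply(seq_len(n_components), function(j) {
    fit_comp(x[comp0 == j], rep(1, sum(comp0 == j)))
  })
  weights <- as.vector(table(factor(comp0, levels = seq_len(n_components)))) / length(x)
  loglik <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(n_components), function(j) {
      weights[j] * dgamma(x, shape = params[[j]]$shape, rate = params[[j]]$rate)
    }, numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    post <- dens / tot
    new_loglik <- sum(log(tot))
    if (is.finite(new_loglik) && abs(new_loglik - loglik) < tol * abs(loglik)) {
      loglik <- new_loglik; converged <- TRUE; break
    }
    loglik <- new_loglik
    weights <- colMeans(post)
    params <- lapply(seq_len(n_components), function(j) fit_comp(x, post[, j]))
  }
  dens <- vapply(seq_len(n_components), function(j) {
    weights[j] * dgamma(x, shape = params[[j]]$shape, rate = params[[j]]$rate)
  }, numeric(length(x)))
  tot <- rowSums(dens); tot[tot == 0] <- .Machine$double.xmin
  list(
    params = params, weights = weights, posterior = dens / tot,
    means = vapply(params, function(p) p$shape / p$rate, numeric(1)),
    loglik = loglik, converged = converged
  )
}

# threshold from one mixture fit: min value among spots assigned with
# > posterior_cut to the target component (second-highest mean when 3
# components: the first signal component above background)
mixture_threshold <- function(values, posterior, means, posterior_cut) {
  ord <- order(means, decreasing = TRUE)
  target <- if (length(means) >= 3) ord[2] else ord[1]
  assigned <- posterior[, target] > posterior_cut
  if (!any(assigned)) return(NA_real_)
  min(values[assigned])
}

#' Binarize cell-type presence per spot from deconvolution output
#'
#' Per cell type and tissue section, fits a gamma mixture to the RNA
#' fractions and a Gaussian mixture to the summed deconvolved expression,
#' takes as threshold the minimum value among spots with > `posterior_cut`
#' probability of the signal component, applies the floors, takes the median
#' threshold across sections, and calls a spot "present" when both the
#' fraction and the expression thresholds are met.
#'
#' @param grid A `spot_grid` with `fractions` and `summed_expr` attached.
#' @param n_components Named vector or single value in {2, 3}; 3 reserves a
#'   middle component for types with a heavy intermediate background.
#' @param posterior_cut Posterior probability needed to anchor the threshold.
#' @param floors `c(fraction, expression)` lower bounds for the thresholds.
#' @return A `presence_mask`: list with logical matrix `mask`
#'   (spots x cell types), tibble `thresholds` (cell_type, fraction_cut,
#'   expr_cut, flag).
#' @export
binarize_presence <- function(grid, n_components = 2, posterior_cut = 0.70,
                              floors = c(fraction = 0.001, expression = 50)) {
  fractions <- require_fractions(grid)
  if (is.null(grid$summed_expr)) abort("binarize_presence needs summed_expr")
  sections <- unique(grid$spot_meta$section_id)
  types <- colnames(fractions)
  if (length(n_components) == 1) {
    n_components <- setNames(rep(n_components, length(types)), types)
  }
  thr_rows <- vector("list", length(types))
  for (t_i in seq_along(types)) {
    ty <- types[t_i]
    ncomp <- n_components[[ty]]
    frac_cuts <- expr_cuts <- numeric(0)
    flag <- NA_character_
    for (sec in sections) {
      in_sec <- grid$spot_meta$section_id == sec
      fr <- fractions[in_sec, ty]
      ex <- grid$summed_expr[in_sec, ty]
      if (sd(fr) < 1e-12 * max(abs(fr), 1) ||
          sd(ex) < 1e-12 * max(abs(ex), 1)) {
        flag <- "single_component"
        next
      }
      fr_fit <- tryCatch(gamma_mixture_em(pmax(fr, 1e-12), ncomp),
                         error = function(e) NULL)
      if (is.null(fr_fit)) { flag <- "gamma_em_failed"; next }
      if (!fr_fit$converged) flag <- "gamma_em_fallback"
      if (diff(range(fr_fit$means)) / max(fr_fit$means) < 1e-3) {
        flag <- "single_component"
        next
      }
      fc <- mixture_threshold(fr, fr_fit$posterior, fr_fit$means, posterior_cut)
      gm <- tryCatch(
        suppressWarnings(Mclust(ex, G = ncomp, modelNames = "V",
                                verbose = FALSE)),
        error = function(e) NULL
      )
      if (is.null(gm)) { flag <- "gaussian_em_failed"; next }
      ec <- mixture_threshold(ex, gm$z, gm$parameters$mean, posterior_cut)
      if (!is.na(fc)) frac_cuts <- c(frac_cuts, max(fc, floors[[1]]))
      if (!is.na(ec)) expr_cuts <- c(expr_cuts, max(ec, floors[[2]]))
    }
    if (!length(frac_cuts) || !length(expr_cuts)) {
      thr_rows[[t_i]] <- tibble(cell_type = ty, fraction_cut = Inf,
                                expr_cut = Inf,
                                flag = flag %||% "absent_everywhere")
    } else {
      thr_rows[[t_i]] <- tibble(cell_type = ty,
                                fraction_cut = median(frac_cuts),
                                expr_cut = median(expr_cuts), flag = flag)
    }
  }
  thresholds <- bind_rows(thr_rows)
  mask <- vapply(seq_along(types), function(t_i) {
    fractions[, types[t_i]] >= thresholds$fraction_cut[t_i] &
      grid$summed_expr[, types[t_i]] >= thresholds$expr_cut[t_i]
  }, logical(nrow(fractions)))
  colnames(mask) <- types
  rownames(mask) <- rownames(fractions)
  structure(list(mask = mask, thresholds = thresholds,
                 posterior_cut = posterior_cut, floors = floors),
            class = "presence_mask")
}

#' @export
print.presence_mask <- function(x, ...) {
  cat(sprintf("<presence_mask> %d spots x %d cell types; presence rates %s\n",
              nrow(x$mask), ncol(x$mask),
              paste(sprintf("%.2f", colMeans(x$mask)), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.presence_mask <- function(x, ...) {
  tibble(
    spot = rep(rownames(x$mask), times = ncol(x$mask)),
    cell_type = rep(colnames(x$mask), each = nrow(x$mask)),
    present = as.vector(x$mask)
  )
}

#' Resampling enrichment of cell-type fractions in a niche
#'
#' Builds an empirical null of mean cell-type fractions over random
#' `n_sample`-spot draws (without replacement within a draw) and reports, per
#' cell type, the empirical probability of a null mean above the niche mean,
#' BH-adjusted across cell types, plus the log2 enrichment of the niche mean
#' over the grand empirical mean.
#'
#' @param fractions Spots x cell-type fraction matrix (all analyzed spots).
#' @param niche Spot selector (logical mask, indices or rownames) of the
#'   niche.
#' @param n_sample Spots per null draw.
#' @param n_iter Null draws.
#' @param seed RNG seed.
#' @param correction `"none"` reproduces the plain fraction-of-iterations
#'   definition (an empirical p of exactly 0 is possible); `"add_one"`
#'   applies the (B+1) correction.
#' @return An `enrichment_result` tibble: cell_type, niche_mean, null_mean,
#'   log2_enrichment, empirical_p, adjusted_p.
#' @export
niche_enrichment <- function(fractions, niche, n_sample = 100, n_iter = 10000,
                             seed = 1L, correction = c("none", "add_one")) {
  correction <- match.arg(correction)
  fractions <- as.matrix(fractions)
  if (is.character(niche)) niche <- rownames(fractions) %in% niche
  if (is.logical(niche)) niche <- which(niche)
  if (!length(niche)) abort("niche is empty")
  if (nrow(fractions) < n_sample) abort("fewer spots than n_sample")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  null_means <- matrix(NA_real_, n_iter, ncol(fractions))
  for (b in seq_len(n_iter)) {
    draw <- sample.int(nrow(fractions), n_sample)
    null_means[b, ] <- colMeans(fractions[draw, , drop = FALSE])
  }
  niche_mean <- colMeans(fractions[niche, , drop = FALSE])
  grand_mean <- colMeans(null_means)
  emp_p <- vapply(seq_len(ncol(fractions)), function(j) {
    hits <- sum(null_means[, j] > niche_mean[j])
    if (correction == "add_one") (hits + 1) / (n_iter + 1) else hits / n_iter
  }, numeric(1))
  undefined <- grand_mean == 0
  if (any(undefined)) {
    warn(paste("zero grand mean; enrichment undefined for:",
               paste(colnames(fractions)[undefined], collapse = ", ")))
  }
  out <- tibble(
    cell_type = colnames(fractions) %||% as.character(seq_len(ncol(fractions))),
    niche_mean = niche_mean,
    null_mean = grand_mean,
    log2_enrichment = ifelse(undefined, NA_real_,
                             log2(niche_mean) - log2(grand_mean)),
    empirical_p = emp_p,
    adjusted_p = p.adjust(emp_p, method = "BH")
  )
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Condition test of program module scores on presence-masked spots
#'
#' Restricts to spots where the program's cell type is present, then runs a
#' two-sided Welch t-test of the module scores between the two conditions;
#' p-values across a program x cell-type grid are adjusted with the chosen
#' method.
#'
#' @param score_list Named list of `module_score`s (or numeric vectors), one
#'   per (cell type, program) combination.
#' @param conditions Per-spot condition labels (two levels).
#' @param mask_list Named list (parallel to `score_list`) of per-spot logical
#'   presence masks for each program's cell type.
#' @param adjust `"BH"` or `"bonferroni"`.
#' @return Tibble: program, t, p, adjusted_p, n_ctrl, n_perturbed.
#' @export
condition_program_test <- function(score_list, conditions,
                                   mask_list, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  conditions <- as.character(conditions)
  lev <- sort(unique(conditions))
  if (length(lev) != 2) abort("exactly two conditions required")
  rows <- purrr::imap(score_list, function(s, nm) {
    sc <- if (inherits(s, "module_score")) s$score else s
    keep <- mask_list[[nm]]
    a <- sc[keep & conditions == lev[1]]
    b <- sc[keep & conditions == lev[2]]
    if (length(a) < 3 || length(b) < 3) {
      abort(sprintf("program %s: fewer than 3 retained spots in a condition", nm))
    }
    tt <- t.test(b, a)
    tibble(program = nm, t = unname(tt$statistic), p = tt$p.value,
           n_ctrl = length(a), n_perturbed = length(b))
  })
  out <- bind_rows(rows)
  out$adjusted_p <- p.adjust(out$p, method = ifelse(adjust == "BH", "BH", "bonferroni"))
  out
}
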