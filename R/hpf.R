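#' Hyperparameters for hierarchical Poisson factorization
#'
#' The generative model places gamma priors on per-cell capacity
#' \eqn{\xi_u \sim Gamma(a', a'/b')}, cell loadings
#' \eqn{\theta_{uk} \sim Gamma(a, \xi_u)}, per-gene capacity
#' \eqn{\eta_i \sim Gamma(c', c'/d')} and gene loadings
#' \eqn{\beta_{ik} \sim Gamma(c, \eta_i)}, with counts
#' \eqn{y_{ui} \sim Poisson(\sum_k \theta_{uk}\beta_{ik})}.
#' Shape defaults of 0.3 encode sparse loadings, the convention for
#' single-cell counts; `b_prime`/`d_prime` default to `NA` and are then set
#' empirically from the data scale at fit time.
#'
#' @param k Number of factors.
#' @param a,a_prime Cell-side shapes.
#' @param c,c_prime Gene-side shapes.
#' @param b_prime,d_prime Rate hyper-priors (`NA` = set from data mean).
#' @param max_iter,tol Convergence controls: stop when the relative ELBO
#'   change drops below `tol` or after `max_iter` sweeps.
#' @param seed Integer seed for the variational initialization.
#' @return An `hpf_hyperparams` list.
#' @export
hpf_hyperparams <- function(k, a = 0.3, a_prime = 1, c = 0.3, c_prime = 1,
                            b_prime = NA_real_, d_prime = NA_real_,
                            max_iter = 500, tol = 1e-5, seed = 1L) {
  stopifnot(k >= 1, a > 0, a_prime > 0, c > 0, c_prime > 0,
            max_iter >= 1, tol > 0)
  structure(
    list(k = as.integer(k), a = a, a_prime = a_prime, c = c, c_prime = c_prime,
         b_prime = b_prime, d_prime = d_prime,
         max_iter = as.integer(max_iter), tol = tol, seed = as.integer(seed)),
    class = "hpf_hyperparams"
  )
}

gamma_entropy <- function(shp, rte) {
  shp - log(rte) + lgamma(shp) + (1 - shp) * digamma(shp)
}

#' Fit hierarchical Poisson factorization by coordinate-ascent VI
#'
#' Runs mean-field coordinate ascent on the HPF model (see
#' [hpf_hyperparams()]) and returns posterior-mean gene scores (genes x k)
#' and cell scores (cells x k). The evidence lower bound is tracked per sweep
#' and is non-decreasing; convergence is declared when its relative change
#' falls below `hyper$tol`.
#'
#' @param counts A `count_matrix` (or plain cells x genes integer matrix).
#' @param hyper An `hpf_hyperparams` object.
#' @return A `factor_model`: gene_scores, cell_scores, capacities `xi`
#'   (cells) and `eta` (genes), `elbo_trace`, `hyper`, `converged`.
#' @export
fit_hpf <- function(counts, hyper) {
  if (inherits(counts, "count_matrix")) {
    cell_ids <- rownames(counts$counts)
    genes <- colnames(counts$counts)
    y_mat <- counts$counts
  } else {
    y_mat <- as.matrix(counts)
    cell_ids <- rownames(y_mat) %||% sprintf("cell%05d", seq_len(nrow(y_mat)))
    genes <- colnames(y_mat) %||% sprintf("g%04d", seq_len(ncol(y_mat)))
  }
  if (any(y_mat < 0) || any(y_mat != round(y_mat))) {
    abort("fit_hpf needs non-negative integer counts")
  }
  if (sum(y_mat) == 0) abort("all-zero count matrix cannot be factorized")
  n <- nrow(y_mat); g <- ncol(y_mat); k <- hyper$k
  if (n < k || g < k) abort("need at least k cells and k genes")

  # empirical rate hyper-priors: prior mean of theta*beta' matches data scale
  b_prime <- hyper$b_prime
  d_prime <- hyper$d_prime
  if (is.na(b_prime) || is.na(d_prime)) {
    mean_y <- mean(y_mat)
    # E[theta] = a/xi with E[xi] = b'... choose symmetric scale s so that
    # k * s^2 = mean_y, with s = a*b'/a' = c*d'/c'
    s <- sqrt(mean_y / k)
    if (is.na(b_prime)) b_prime <- s * hyper$a_prime / hyper$a
    if (is.na(d_prime)) d_prime <- s * hyper$c_prime / hyper$c
  }

  nz <- which(y_mat > 0)
  u_idx <- ((nz - 1) %% n) + 1L
  i_idx <- ((nz - 1) %/% n) + 1L
  y <- y_mat[nz]

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(hyper$seed)

  # variational gamma parameters, jittered for symmetry breaking
  jit <- function(nr, nc, base) matrix(base * (0.5 + runif(nr * nc)), nr, nc)
  g_shp <- jit(n, k, hyper$a)              # q(theta)
  g_rte <- jit(n, k, hyper$a_prime / b_prime)
  l_shp <- jit(g, k, hyper$c)              # q(beta)
  l_rte <- jit(g, k, hyper$c_prime / d_prime)
  k_shp <- hyper$a_prime + k * hyper$a     # q(xi) shape, fixed
  t_shp <- hyper$c_prime + k * hyper$c     # q(eta) shape, fixed
  k_rte <- rep(hyper$a_prime / b_prime + k * hyper$a / (hyper$a_prime / b_prime), n)
  t_rte <- rep(hyper$c_prime / d_prime + k * hyper$c / (hyper$c_prime / d_prime), g)

  fit <- .hpf_cavi(u_idx - 1L, i_idx - 1L, y,
                   g_shp, g_rte, l_shp, l_rte, k_rte, t_rte,
                   hyper$a, hyper$a_prime, hyper$c, hyper$c_prime,
                   b_prime, d_prime, hyper$max_iter, hyper$tol)
  elbo_trace <- fit$elbo_trace
  converged <- fit$converged
  k_rte <- as.vector(fit$k_rte); t_rte <- as.vector(fit$t_rte)
  k_shp <- fit$k_shp; t_shp <- fit$t_shp

  cell_scores <- fit$g_shp / fit$g_rte
  gene_scores <- fit$l_shp / fit$l_rte
  dimnames(cell_scores) <- list(cell_ids, paste0("factor_", seq_len(k)))
  dimnames(gene_scores) <- list(genes, paste0("factor_", seq_len(k)))
  structure(
    list(gene_scores = gene_scores, cell_scores = cell_scores,
         xi = as.vector(k_shp / k_rte), eta = as.vector(t_shp / t_rte),
         elbo_trace = elbo_trace, hyper = hyper, converged = converged),
    class = "factor_model"
  )
}

rowsum_by <- function(x, idx, n_out) {
  out <- rowsum(x, idx)
  full <- matrix(0, n_out, ncol(x))
  full[as.integer(rownames(out)), ] <- out
  full
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a factor model from known score matrices
#'
#' Wraps externally obtained (e.g. planted ground-truth) gene and cell scores
#' in the same container [fit_hpf()] returns, so every downstream operation
#' can run on them.
#'
#' @param gene_scores Genes x k non-negative matrix.
#' @param cell_scores Cells x k non-negative matrix.
#' @param hyper Optional `hpf_hyperparams`.
#' @return A `factor_model`.
#' @export
factor_model_from_scores <- function(gene_scores, cell_scores, hyper = NULL) {
  gene_scores <- as.matrix(gene_scores); cell_scores <- as.matrix(cell_scores)
  stopifnot(ncol(gene_scores) == ncol(cell_scores),
            all(gene_scores >= 0), all(cell_scores >= 0))
  k <- ncol(gene_scores)
  if (is.null(colnames(gene_scores))) {
    colnames(gene_scores) <- colnames(cell_scores) <- paste0("factor_", seq_len(k))
  }
  if (is.null(rownames(gene_scores))) {
    rownames(gene_scores) <- sprintf("g%04d", seq_len(nrow(gene_scores)))
  }
  if (is.null(rownames(cell_scores))) {
    rownames(cell_scores) <- sprintf("cell%05d", seq_len(nrow(cell_scores)))
  }
  structure(
    list(gene_scores = gene_scores, cell_scores = cell_scores,
         xi = NULL, eta = NULL, elbo_trace = numeric(0),
         hyper = hyper %||% hpf_hyperparams(k), converged = NA),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf(
    "<factor_model> k = %d; %d genes x %d cells; %d CAVI sweeps%s\n",
    ncol(x$gene_scores), nrow(x$gene_scores), nrow(x$cell_scores),
    length(x$elbo_trace),
    if (isTRUE(x$converged)) " (converged)" else ""
  ))
  invisible(x)
}

#' Tidy gene or cell scores of a factor model
#' @param x A `factor_model`.
#' @param matrix Which score matrix to return in long form.
#' @param ... Unused.
#' @return Tibble with `gene` (or `cell_id`), `factor`, `score`.
#' @export
tidy.factor_model <- function(x, matrix = c("gene", "cell"), ...) {
  matrix <- match.arg(matrix)
  m <- if (matrix == "gene") x$gene_scores else x$cell_scores
  id_col <- if (matrix == "gene") "gene" else "cell_id"
  out <- tibble(
    rep(rownames(m), times = ncol(m)),
    factor = rep(colnames(m), each = nrow(m)),
    score = as.vector(m)
  )
  names(out)[1] <- id_col
  out
}

#' One-row fit summary of a factor model
#' @param x A `factor_model`.
#' @param ... Unused.
#' @return Tibble with k, dims, sweeps, final ELBO and convergence flag.
#' @export
glance.factor_model <- function(x, ...) {
  tibble(
    k = ncol(x$gene_scores),
    n_genes = nrow(x$gene_scores),
    n_cells = nrow(x$cell_scores),
    n_iter = length(x$elbo_trace),
    elbo = if (length(x$elbo_trace)) x$elbo_trace[length(x$elbo_trace)] else NA_real_,
    converged = x$converged
  )
}

#' ELBO trace plot for a fitted factor model
#' @param object A `factor_model` from [fit_hpf()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.factor_model <- function(object, ...) {
  df <- tibble(sweep = seq_along(object$elbo_trace), elbo = object$elbo_trace)
  ggplot(df, aes(x = .data$sweep, y = .data$elbo)) +
    geom_line() +
    labs(x = "CAVI sweep", y = "evidence lower bound") +
    theme_minimal()
}
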