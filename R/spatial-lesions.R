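#' Cluster tumor spots into transcriptional-state groups
#'
#' Z-scores the tumor-state fractions across tumor spots, computes Pearson
#' correlation distance (1 - r) between spots, and cuts an average-linkage
#' hierarchical tree at `k_states` groups.
#'
#' @param tumor_fractions Tumor spots x tumor-state fraction matrix (already
#'   restricted to above-background tumor spots).
#' @param k_states Number of state clusters.
#' @param zscore_first Z-score fractions per state before clustering.
#' @return Integer cluster labels, one per tumor spot.
#' @export
cluster_tumor_spots <- function(tumor_fractions, k_states = 7,
                                zscore_first = TRUE) {
  m <- as.matrix(tumor_fractions)
  if (nrow(m) < k_states) abort("fewer tumor spots than k_states")
  if (k_states == 1) return(rep(1L, nrow(m)))
  if (zscore_first) m <- scale(m)
  m <- m[, !apply(m, 2, function(col) any(!is.finite(col))), drop = FALSE]
  if (ncol(m) < 2) abort("need at least two informative tumor states")
  if (any(apply(m, 1, sd) == 0)) {
    abort("spot(s) with constant state profile: correlation distance undefined; drop them or disable z-scoring")
  }
  d <- as.dist(1 - cor(t(m)))
  cutree(hclust(d, method = "average"), k = k_states)
}

#' Label state clusters by their dominant tumor state
#'
#' Each cluster is labeled with the tumor state of highest mean fraction;
#' configured label pairs are merged (for states known to blend) before
#' lesion segmentation. Exact ties break deterministically by column order
#' and are logged.
#'
#' @param state_cluster Integer cluster labels per tumor spot.
#' @param tumor_fractions Tumor spots x state fraction matrix.
#' @param merge_pairs Optional list of length-2 character vectors of state
#'   labels to unify (the merged label joins both with `"+"`).
#' @return Tibble (cluster, label) plus a per-spot `spot_label` attribute.
#' @export
label_clusters <- function(state_cluster, tumor_fractions, merge_pairs = NULL) {
  m <- as.matrix(tumor_fractions)
  states <- colnames(m) %||% paste0("state_", seq_len(ncol(m)))
  colnames(m) <- states
  labs <- vapply(sort(unique(state_cluster)), function(cl) {
    mu <- colMeans(m[state_cluster == cl, , drop = FALSE])
    top <- which(mu == max(mu))
    if (length(top) > 1) {
      inform(sprintf("cluster %s: tie between %s; first by state order kept",
                     cl, paste(states[top], collapse = ", ")))
    }
    states[top[1]]
  }, character(1))
  out <- tibble(cluster = sort(unique(state_cluster)), label = labs)
  if (!is.null(merge_pairs)) {
    for (pair in merge_pairs) {
      merged <- paste(sort(pair), collapse = "+")
      out$label[out$label %in% pair] <- merged
    }
  }
  out
}

# lattice adjacency: TRUE if spots p and q are neighbors
# square: rook (4-neighbor). hex: Visium even/odd offset rows, neighbors
# (r, c +/- 2), (r +/- 1, c +/- 1).
lattice_neighbors <- function(row_a, col_a, row_b, col_b,
                              lattice = c("square", "hex")) {
  lattice <- match.arg(lattice)
  dr <- abs(row_a - row_b); dc <- abs(col_a - col_b)
  if (lattice == "square") {
    (dr + dc) == 1
  } else {
    (dr == 0 & dc == 2) | (dr == 1 & dc == 1)
  }
}

build_adjacency_graph <- function(meta, lattice) {
  n <- nrow(meta)
  edges <- integer(0)
  # bucket by coordinate for O(n) neighbor lookup
  key <- paste(meta$section_id, meta$array_row, meta$array_col, sep = "\r")
  idx <- setNames(seq_len(n), key)
  offsets <- if (lattice == "square") {
    list(c(0, 1), c(1, 0))
  } else {
    list(c(0, 2), c(1, 1), c(1, -1))
  }
  for (off in offsets) {
    nb_key <- paste(meta$section_id, meta$array_row + off[1],
                    meta$array_col + off[2], sep = "\r")
    hit <- idx[nb_key]
    ok <- !is.na(hit)
    edges <- c(edges, rbind(which(ok), unname(hit[ok])))
  }
  igraph::make_graph(edges, n = n, directed = FALSE)
}

#' Segment contiguous lesion areas
#'
#' Finds maximal connected components of same-labeled tumor spots under the
#' lattice adjacency and discards components with at most `min_spots` spots
#' (strictly larger components are retained).
#'
#' @param spot_meta Tibble of the tumor spots with `array_row`, `array_col`,
#'   `section_id`.
#' @param labels Per-tumor-spot state labels (cluster labels after
#'   [label_clusters()] merging).
#' @param lattice `"square"` (rook adjacency) or `"hex"` (Visium offset rows).
#' @param min_spots Components must exceed this size to be kept.
#' @return A `lesion_map` tibble: one row per tumor spot with `lesion_id`
#'   (NA when the component was discarded), `lesion_label`, `lesion_size`.
#' @export
lesion_components <- function(spot_meta, labels, lattice = c("square", "hex"),
                              min_spots = 6) {
  lattice <- match.arg(lattice)
  spot_meta <- as_tibble(spot_meta)
  stopifnot(nrow(spot_meta) == length(labels))
  g <- build_adjacency_graph(spot_meta, lattice)
  # cut edges between different labels, then take components
  el <- igraph::as_edgelist(g, names = FALSE)
  same <- labels[el[, 1]] == labels[el[, 2]]
  g2 <- igraph::subgraph_from_edges(g, which(same), delete.vertices = FALSE)
  comp <- igraph::components(g2)$membership
  sizes <- table(comp)
  keep <- sizes > min_spots
  lesion_id <- ifelse(keep[as.character(comp)], comp, NA_integer_)
  # renumber retained lesions consecutively
  lesion_id <- as.integer(factor(lesion_id))
  out <- spot_meta
  out$state_label <- as.character(labels)
  out$lesion_id <- lesion_id
  out$lesion_label <- ifelse(is.na(lesion_id), NA_character_, out$state_label)
  out$lesion_size <- ifelse(is.na(lesion_id), NA_integer_,
                            as.integer(sizes[as.character(comp)]))
  class(out) <- c("lesion_map", class(out))
  out
}

#' Spatial plot of lesion areas
#' @param object A `lesion_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lesion_map <- function(object, ...) {
  ggplot(object, aes(x = .data$array_col, y = .data$array_row,
                     fill = .data$lesion_label)) +
    geom_tile() +
    coord_equal() +
    facet_wrap(~section_id) +
    labs(x = "array column", y = "array row", fill = "lesion state") +
    theme_minimal()
}

#' Flag lesions with a detectable immune response
#'
#' A lesion responds when strictly more than `threshold` of its spots belong
#' to the inflammatory-cytokine or interferon signaling niche.
#'
#' @param lesions A `lesion_map`.
#' @param niche A `niche_call` for the same spots (row-aligned).
#' @param threshold Fraction of niche spots needed.
#' @return Tibble (lesion_id, lesion_label, n_spots, n_niche_spots,
#'   niche_fraction, immune_response).
#' @export
classify_immune_response <- function(lesions, niche, threshold = 0.10) {
  stopifnot(nrow(lesions) == nrow(niche))
  in_niche <- niche$ic | niche$ifn
  lesions %>%
    filter(!is.na(.data$lesion_id)) %>%
    mutate(in_niche = in_niche[!is.na(lesions$lesion_id)]) %>%
    group_by(.data$lesion_id, .data$lesion_label) %>%
    summarise(
      n_spots = n(),
      n_niche_spots = sum(.data$in_niche),
      .groups = "drop"
    ) %>%
    mutate(
      niche_fraction = .data$n_niche_spots / .data$n_spots,
      immune_response = .data$niche_fraction > threshold
    )
}

#' Spot-level differential expression between lesion groups
#'
#' Tests genes that are detected in at least `detect_frac` of spots in either
#' group and have an absolute mean log-normalized difference above
#' `prefilter_lfc`, using the two-sided Wilcoxon rank-sum test with BH
#' adjustment. Genes significant at `adjusted_p < sig_alpha` and
#' `|lfc| > sig_lfc` are labeled by direction.
#'
#' @param lognorm Spots x genes log-normalized matrix.
#' @param group_a,group_b Spot selectors (logical, indices or rownames) of
#'   the two lesion groups (e.g. responding vs non-responding spots).
#' @param detect_frac Detection prefilter.
#' @param prefilter_lfc Mean-difference prefilter.
#' @param sig_alpha,sig_lfc Significance thresholds for the `significant`
#'   label.
#' @return A `spot_de_result` tibble: gene, lfc (a - b), p, adjusted_p,
#'   detect_frac_a, detect_frac_b, significant ("up_a", "up_b", or NA).
#' @export
lesion_de <- function(lognorm, group_a, group_b, detect_frac = 0.10,
                      prefilter_lfc = 0.25, sig_alpha = 0.01, sig_lfc = 0.5) {
  sel <- function(g) {
    if (is.character(g)) which(rownames(lognorm) %in% g)
    else if (is.logical(g)) which(g)
    else g
  }
  ia <- sel(group_a); ib <- sel(group_b)
  if (!length(ia) || !length(ib)) abort("both spot groups must be non-empty")
  xa <- lognorm[ia, , drop = FALSE]; xb <- lognorm[ib, , drop = FALSE]
  det_a <- colMeans(xa > 0); det_b <- colMeans(xb > 0)
  lfc <- colMeans(xa) - colMeans(xb)
  testable <- (det_a >= detect_frac | det_b >= detect_frac) &
    abs(lfc) > prefilter_lfc
  if (!any(testable)) {
    inform("no gene passed the DE prefilters")
    return(tibble(gene = character(), lfc = double(), p = double(),
                  adjusted_p = double(), detect_frac_a = double(),
                  detect_frac_b = double(), significant = character()))
  }
  genes <- colnames(lognorm)[testable]
  p <- vapply(genes, function(g) mann_whitney(xa[, g], xb[, g])$p, numeric(1))
  out <- tibble(
    gene = genes, lfc = lfc[testable], p = p,
    adjusted_p = p.adjust(p, method = "BH"),
    detect_frac_a = det_a[testable], detect_frac_b = det_b[testable]
  )
  out$significant <- dplyr::case_when(
    out$adjusted_p < sig_alpha & out$lfc > sig_lfc ~ "up_a",
    out$adjusted_p < sig_alpha & out$lfc < -sig_lfc ~ "up_b",
    TRUE ~ NA_character_
  )
  class(out) <- c("spot_de_result", class(out))
  out
}
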