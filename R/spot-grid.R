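#' Assemble a spatial spot grid
#'
#' Container for spot-level spatial transcriptomics: raw counts, array
#' coordinates, optional log-normalized expression, and (if a deconvolution
#' step has been run upstream) per-spot cell-type RNA fractions and summed
#' deconvolved expression totals.
#'
#' @param counts Spots x genes non-negative integer matrix.
#' @param spot_meta Data frame with `spot_id`, `array_row`, `array_col`,
#'   `section_id` and optionally `condition`. Coordinates must be unique
#'   within a section.
#' @param fractions Optional spots x cell-type matrix of RNA fractions; rows
#'   must sum to 1 within 1e-6.
#' @param summed_expr Optional spots x cell-type matrix of summed deconvolved
#'   expression.
#' @param lognorm Optional spots x genes log-normalized matrix; computed
#'   lazily by [normalize_counts()] consumers when absent.
#' @return A `spot_grid` object.
#' @export
spot_grid <- function(counts, spot_meta, fractions = NULL, summed_expr = NULL,
                      lognorm = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  spot_meta <- as_tibble(spot_meta)
  need <- c("spot_id", "array_row", "array_col", "section_id")
  if (!all(need %in% names(spot_meta))) {
    abort(paste("spot_meta needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(spot_meta) != nrow(counts)) abort("one metadata row per spot required")
  key <- paste(spot_meta$section_id, spot_meta$array_row, spot_meta$array_col)
  if (anyDuplicated(key)) abort("array coordinates must be unique within a section")
  rownames(counts) <- spot_meta$spot_id
  if (!is.null(fractions)) {
    fractions <- as.matrix(fractions)
    if (nrow(fractions) != nrow(counts)) abort("fractions: one row per spot")
    if (any(fractions < 0) || any(fractions > 1)) abort("fractions must lie in [0, 1]")
    if (any(abs(rowSums(fractions) - 1) > 1e-6)) {
      abort("fraction rows must sum to 1 (tolerance 1e-6)")
    }
    rownames(fractions) <- spot_meta$spot_id
  }
  if (!is.null(summed_expr)) {
    summed_expr <- as.matrix(summed_expr)
    if (any(summed_expr < 0)) abort("summed_expr must be non-negative")
    rownames(summed_expr) <- spot_meta$spot_id
  }
  structure(
    list(counts = counts, spot_meta = spot_meta, fractions = fractions,
         summed_expr = summed_expr, lognorm = lognorm),
    class = "spot_grid"
  )
}

#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf(
    "<spot_grid> %d spots x %d genes; %d section(s); fractions: %s\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$spot_meta$section_id)),
    if (is.null(x$fractions)) "absent" else paste(ncol(x$fractions), "cell types")
  ))
  invisible(x)
}

#' @export
dim.spot_grid <- function(x) dim(x$counts)

spot_lognorm <- function(grid) {
  if (!is.null(grid$lognorm)) return(grid$lognorm)
  lognorm_matrix(grid$counts)
}

require_fractions <- function(grid) {
  if (is.null(grid$fractions)) {
    abort("this operation needs per-spot cell-type fractions; none are attached")
  }
  grid$fractions
}
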