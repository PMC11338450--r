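#' Filter low-abundance genes
#'
#' Keeps exactly the genes detected (non-zero count) in at least `min_cells`
#' cells. The cell set and the relative order of surviving genes are
#' unchanged.
#'
#' @param x a [count_matrix()].
#' @param min_cells minimum number of cells with a non-zero count (>= 1).
#' @return a filtered [count_matrix()].
#' @export
filter_genes <- function(x, min_cells = 3) {
  stopifnot(inherits(x, "CountMatrix"))
  if (!is.numeric(min_cells) || min_cells < 1) {
    stop("`min_cells` must be >= 1", call. = FALSE)
  }
  keep <- rowSums(x$values != 0) >= min_cells
  if (!any(keep)) {
    stop(sprintf("no gene is detected in at least %d cells", min_cells),
         call. = FALSE)
  }
  count_matrix(x$values[keep, , drop = FALSE],
               gene_ids = x$gene_ids[keep], cell_ids = x$cell_ids)
}

#' Median-library log normalization
#'
#' Rescales every cell to the median library size and log-transforms:
#' entry (g, c) becomes `ln(m * x_gc / t_c + 1)` where `t_c` is the total
#' count of cell `c` and `m` is the median of all cell totals. Zeros map to
#' zeros exactly. Cells with zero total count cannot be normalized and are
#' dropped first (recorded in provenance).
#'
#' @param x a [count_matrix()].
#' @param min_cells recorded filtering threshold for provenance only (the
#'   actual gene filtering is [filter_genes()]).
#' @return a [processed_matrix()].
#' @export
log_normalize <- function(x, min_cells = NA) {
  stopifnot(inherits(x, "CountMatrix"))
  totals <- colSums(x$values)
  dropped <- x$cell_ids[totals == 0]
  if (length(dropped)) {
    keep <- totals > 0
    x <- count_matrix(x$values[, keep, drop = FALSE],
                      gene_ids = x$gene_ids, cell_ids = x$cell_ids[keep])
    totals <- totals[keep]
  }
  if (any(totals == 0)) {
    stop("zero-total cell present after filtering", call. = FALSE)
  }
  m <- stats::median(totals)
  vals <- log1p(sweep(x$values, 2, m / totals, `*`))
  processed_matrix(
    vals, gene_ids = x$gene_ids, cell_ids = x$cell_ids,
    provenance = list(
      min_cells = min_cells,
      median_library_size = m,
      dropped_zero_total_cells = length(dropped)
    )
  )
}

#' Select highly variable genes
#'
#' Retains the `n_top` genes with the largest per-gene variance of the
#' log-normalized values (default criterion), or the largest dispersion
#' (variance / mean) when `method = "dispersion"`. Relative gene order is
#' preserved and ties at the cutoff go to the gene earlier in input order.
#'
#' @param x a [processed_matrix()].
#' @param n_top HVG budget; `min(n_top, nrow)` genes are kept.
#' @param method ranking statistic, `"variance"` (default) or
#'   `"dispersion"`.
#' @return a [processed_matrix()] restricted to the selected genes.
#' @export
select_hvgs <- function(x, n_top = 2000,
                        method = c("variance", "dispersion")) {
  stopifnot(inherits(x, "ProcessedMatrix"))
  method <- match.arg(method)
  if (!is.numeric(n_top) || n_top < 1) {
    stop("`n_top` must be >= 1", call. = FALSE)
  }
  g <- nrow(x$values)
  n_keep <- min(n_top, g)
  score <- apply(x$values, 1, stats::var)
  if (method == "dispersion") {
    mu <- rowMeans(x$values)
    score <- ifelse(mu > 0, score / mu, 0)
  }
  # ties broken by original order: order() is stable on the index tiebreak
  ranked <- order(-score, seq_len(g))
  keep <- sort(ranked[seq_len(n_keep)])
  prov <- x$provenance
  prov$hvg_n <- n_keep
  prov$hvg_method <- method
  processed_matrix(x$values[keep, , drop = FALSE],
                   gene_ids = x$gene_ids[keep], cell_ids = x$cell_ids,
                   provenance = prov)
}

#' Full preprocessing pipeline: filter, log-normalize, select HVGs
#'
#' @param x a [count_matrix()].
#' @param min_cells gene detection threshold for [filter_genes()].
#' @param hvg_n HVG budget for [select_hvgs()].
#' @param hvg_method HVG ranking statistic.
#' @return a [processed_matrix()].
#' @export
preprocess_counts <- function(x, min_cells = 3, hvg_n = 2000,
                              hvg_method = "variance") {
  x <- filter_genes(x, min_cells = min_cells)
  p <- log_normalize(x, min_cells = min_cells)
  select_hvgs(p, n_top = hvg_n, method = hvg_method)
}
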