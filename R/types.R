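#' Construct a raw count matrix container
#'
#' A `CountMatrix` holds a non-negative gene-by-cell count matrix together
#' with unique gene and cell identifiers. It is the entry point of the
#' imputation pipeline: raw UMI/read counts before any normalization.
#'
#' @param values numeric matrix, genes in rows and cells in columns. All
#'   entries must be finite and non-negative.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   Defaults to the rownames of `values`.
#' @param cell_ids character vector of unique cell identifiers, one per
#'   column. Defaults to the colnames of `values`.
#' @return an object of class `CountMatrix` with fields `values`, `gene_ids`,
#'   `cell_ids`.
#' @export
count_matrix <- function(values,
                         gene_ids = rownames(values),
                         cell_ids = colnames(values)) {
  values <- as_dense_matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  validate_axis_ids(gene_ids, nrow(values), "gene")
  validate_axis_ids(cell_ids, ncol(values), "cell")
  validate_counts(values)
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids),
    class = "CountMatrix"
  )
}

#' Construct a processed (log-normalized) expression matrix
#'
#' A `ProcessedMatrix` is the filtered, log-normalized, optionally
#' HVG-restricted matrix that enters factorization. Entries are non-negative
#' reals (`log1p` of a non-negative quantity) and zeros of the raw matrix map
#' to zeros here. `provenance` records what was done to obtain it.
#'
#' @param values non-negative numeric matrix, genes x cells.
#' @param gene_ids,cell_ids identifiers as in [count_matrix()].
#' @param provenance named list recording filtering threshold, dropped cells,
#'   the median library size used for normalization, and the HVG budget.
#' @return an object of class `ProcessedMatrix`.
#' @export
processed_matrix <- function(values,
                             gene_ids = rownames(values),
                             cell_ids = colnames(values),
                             provenance = list()) {
  values <- as_dense_matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  validate_axis_ids(gene_ids, nrow(values), "gene")
  validate_axis_ids(cell_ids, ncol(values), "cell")
  if (any(!is.finite(values))) {
    stop("processed matrix contains non-finite entries", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("processed matrix contains negative entries", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         provenance = provenance),
    class = "ProcessedMatrix"
  )
}

#' @export
print.CountMatrix <- function(x, ...) {
  nz <- sum(x$values != 0)
  cat(sprintf(
    "CountMatrix: %d genes x %d cells, %d non-zero entries (%.1f%% zeros)\n",
    nrow(x$values), ncol(x$values), nz,
    100 * (1 - nz / length(x$values))
  ))
  invisible(x)
}

#' @export
print.ProcessedMatrix <- function(x, ...) {
  cat(sprintf(
    "ProcessedMatrix: %d genes x %d cells (%.1f%% zeros)\n",
    nrow(x$values), ncol(x$values),
    100 * mean(x$values == 0)
  ))
  if (length(x$provenance)) {
    keys <- names(x$provenance)
    cat("  provenance:", paste(keys, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' @export
dim.ProcessedMatrix <- function(x) dim(x$values)

# internal: coerce Matrix/sparse/data.frame input to a dense base matrix
as_dense_matrix <- function(values) {
  if (inherits(values, "Matrix")) {
    values <- as.matrix(values)
  } else if (is.data.frame(values)) {
    values <- as.matrix(values)
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  storage.mode(values) <- "double"
  values
}

validate_axis_ids <- function(ids, n, axis) {
  if (length(ids) != n) {
    stop(sprintf("%s_ids has length %d but the matrix has %d %ss",
                 axis, length(ids), n, axis), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate %s identifiers", axis), call. = FALSE)
  }
}

validate_counts <- function(values) {
  if (any(!is.finite(values))) {
    stop("count matrix contains non-finite entries", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("count matrix contains negative entries", call. = FALSE)
  }
}

# internal: accept a ProcessedMatrix/CountMatrix or a bare matrix
get_values <- function(x) {
  if (inherits(x, c("CountMatrix", "ProcessedMatrix"))) x$values else
    as_dense_matrix(x)
}
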