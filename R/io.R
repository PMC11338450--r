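#' Read a gene-by-cell count matrix from disk
#'
#' Supports the 10x-style Matrix Market layout (a directory holding
#' `matrix.mtx`, a gene list and a barcode list) and dense CSV/TSV with genes
#' in rows, a header row of cell identifiers and the gene identifier in the
#' first column. Values are read back exactly; a sparse zero and an explicit
#' zero are indistinguishable downstream.
#'
#' @param path file (csv/tsv) or directory (mtx_dir).
#' @param format one of `"mtx_dir"`, `"csv"`, `"tsv"`. Defaults to a guess
#'   from `path`: a directory implies `mtx_dir`, otherwise the file
#'   extension decides.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, format = c("auto", "mtx_dir", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx_dir"
      else if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv"
      else "csv"
  }
  if (format == "mtx_dir") {
    if (!dir.exists(path)) stop("directory not found: ", path, call. = FALSE)
    return(read_counts_mtx_dir(path))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, row.names = 1,
                          comment.char = "", quote = "\"")
  values <- as.matrix(df)
  if (!is.numeric(values)) {
    stop("non-numeric entries in count table", call. = FALSE)
  }
  count_matrix(values, gene_ids = rownames(df), cell_ids = colnames(df))
}

read_counts_mtx_dir <- function(path) {
  mtx <- first_existing(path, c("matrix.mtx", "counts.mtx"))
  genes <- first_existing(path, c("genes.tsv", "features.tsv", "genes.txt"))
  cells <- first_existing(path, c("barcodes.tsv", "barcodes.txt", "cells.tsv"))
  m <- as.matrix(Matrix::readMM(mtx))
  gene_tab <- utils::read.table(genes, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
  cell_tab <- utils::read.table(cells, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
  count_matrix(m, gene_ids = gene_tab[[1]], cell_ids = cell_tab[[1]])
}

first_existing <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("none of [", paste(candidates, collapse = ", "),
       "] found in ", dir, call. = FALSE)
}

#' Write a count or expression matrix to disk
#'
#' @param x a [count_matrix()], [processed_matrix()] or bare matrix with
#'   dimnames.
#' @param path output file (csv/tsv) or directory (mtx_dir; created).
#' @param format `"csv"`, `"tsv"` or `"mtx_dir"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("csv", "tsv", "mtx_dir")) {
  format <- match.arg(format)
  values <- get_values(x)
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(values), file.path(path, "genes.tsv"))
    writeLines(colnames(values), file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene = rownames(values), values, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  }
  invisible(path)
}

#' Write a processed matrix with its provenance sidecar
#'
#' The matrix goes to `<path>` (CSV) and the provenance record to
#' `<path>.provenance.txt` as flat `key = value` lines.
#'
#' @param x a [processed_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_processed <- function(x, path) {
  stopifnot(inherits(x, "ProcessedMatrix"))
  write_counts(x, path, format = "csv")
  write_flat_config(x$provenance, paste0(path, ".provenance.txt"))
  invisible(path)
}

# flat key = value serialization used for provenance / run configs / params
write_flat_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 15), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  out <- lapply(vals, function(v) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  names(out) <- keys
  out
}
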