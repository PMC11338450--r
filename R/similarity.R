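#' Cosine similarity between the rows of a matrix
#'
#' Entry (i, j) is `dot(v_i, v_j) / (||v_i|| * ||v_j||)`. All-zero rows get
#' self-similarity 1 and cross-similarity 0; the diagonal is forced to 1.
#'
#' @param vectors numeric matrix whose rows are the vectors to compare.
#' @return a symmetric square matrix with unit diagonal.
#' @export
cosine_sim <- function(vectors) {
  vectors <- as_dense_matrix(vectors)
  norms <- sqrt(rowSums(vectors^2))
  safe <- ifelse(norms > 0, norms, 1)
  s <- tcrossprod(vectors / safe)
  s[norms == 0, ] <- 0
  s[, norms == 0] <- 0
  diag(s) <- 1
  (s + t(s)) / 2
}

#' Pearson correlation similarity between the rows of a matrix
#'
#' Entry (i, j) is the Pearson correlation of rows i and j. Constant rows
#' (zero variance) are assigned correlation 0 to every other vector and 1 to
#' themselves.
#'
#' @param vectors numeric matrix whose rows are the vectors to compare;
#'   at least two columns.
#' @return a symmetric square matrix with unit diagonal.
#' @export
corr_sim <- function(vectors) {
  vectors <- as_dense_matrix(vectors)
  if (ncol(vectors) < 2) stop("vectors must have length >= 2", call. = FALSE)
  s <- suppressWarnings(stats::cor(t(vectors)))
  s[!is.finite(s)] <- 0
  diag(s) <- 1
  (s + t(s)) / 2
}

#' Build the gene-gene and cell-cell similarity graphs
#'
#' Both graphs average cosine and Pearson similarity and then clip negative
#' entries to zero (multiplicative updates need non-negative graph weights):
#' `K_G = clip0((cos + cor)/2)` over gene rows, `K_C` analogously over cell
#' columns. Diagonals are forced to 1.
#'
#' @param x a [processed_matrix()] (or bare matrix), genes x cells.
#' @return an object of class `SimilarityGraphs` with fields `K_G` (genes x
#'   genes) and `K_C` (cells x cells); entries in `[0, 1]`, unit diagonal.
#' @export
build_graphs <- function(x) {
  v <- get_values(x)
  if (length(v) == 0) stop("empty matrix", call. = FALSE)
  K_G <- average_clip(cosine_sim(v), corr_sim(v))
  tv <- t(v)
  K_C <- average_clip(cosine_sim(tv), corr_sim(tv))
  structure(list(K_G = K_G, K_C = K_C), class = "SimilarityGraphs")
}

average_clip <- function(a, b) {
  s <- (a + b) / 2
  s[s < 0] <- 0
  s[s > 1] <- 1
  diag(s) <- 1
  (s + t(s)) / 2
}

#' @export
print.SimilarityGraphs <- function(x, ...) {
  cat(sprintf("SimilarityGraphs: K_G %dx%d, K_C %dx%d\n",
              nrow(x$K_G), ncol(x$K_G), nrow(x$K_C), ncol(x$K_C)))
  invisible(x)
}
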