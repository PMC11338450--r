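#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions
#' (up to label renaming), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return scalar ARI (<= 1).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies (the common library default); 1 for identical partitions, 0
#' when either partition is trivial or the partitions are independent.
#'
#' @param a,b label vectors of equal length.
#' @return scalar NMI in `[0, 1]`.
#' @export
norm_mutual_info <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / (pa %o% pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  denom <- (ha + hb) / 2
  if (denom == 0) return(0)
  max(0, min(1, mi / denom))
}

#' Recovery metrics against the normalized true expression
#'
#' RMSE over all entries and one global Pearson correlation over the
#' flattened matrices.
#'
#' @param imputed imputed matrix.
#' @param truth_norm log-normalized true counts (same shape).
#' @return named list `rmse`, `pcc`.
#' @export
recovery_metrics <- function(imputed, truth_norm) {
  vi <- get_values(imputed)
  vt <- get_values(truth_norm)
  if (!all(dim(vi) == dim(vt))) stop("shape mismatch", call. = FALSE)
  rmse <- sqrt(mean((vi - vt)^2))
  pcc <- if (stats::sd(vi) == 0 || stats::sd(vt) == 0) {
    warning("constant input: PCC undefined, reported as 0", call. = FALSE)
    0
  } else {
    stats::cor(as.vector(vi), as.vector(vt))
  }
  list(rmse = rmse, pcc = pcc)
}

#' K-means clustering of cells scored against known labels
#'
#' Runs K-means on the cells (columns as observations over gene features)
#' with `n_init` seeded k-means++ restarts (the initialization of the
#' mainstream K-means implementations), keeps the best-inertia solution, and
#' scores it with ARI and NMI against the true labels.
#'
#' @param x matrix (genes x cells) or [processed_matrix()].
#' @param labels true group label per cell.
#' @param n_clusters number of clusters; defaults to the number of distinct
#'   labels.
#' @param seed RNG seed for the restarts.
#' @param n_init number of restarts.
#' @return named list `ari`, `nmi`, and the cluster assignment `cluster`.
#' @export
cluster_and_score <- function(x, labels, n_clusters = NULL, seed = 1,
                              n_init = 20) {
  v <- get_values(x)
  if (length(labels) != ncol(v)) {
    stop("`labels` must have one entry per cell", call. = FALSE)
  }
  if (is.null(n_clusters)) n_clusters <- length(unique(labels))
  if (ncol(v) < n_clusters) {
    stop("fewer cells than clusters", call. = FALSE)
  }
  km <- withr::with_seed(seed, kmeans_pp(t(v), n_clusters, n_init))
  list(ari = adjusted_rand_index(km$cluster, labels),
       nmi = norm_mutual_info(km$cluster, labels),
       cluster = km$cluster)
}

# K-means with k-means++ initialization and n_init restarts, best inertia
# kept. Lloyd fallback guards the rare Hartigan-Wong "quick-transfer" and
# empty-cluster failures. Uses the current RNG state (callers seed it).
kmeans_pp <- function(obs, k, n_init, iter.max = 100) {
  n <- nrow(obs)
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- matrix(0, k, ncol(obs))
    centers[1, ] <- obs[sample.int(n, 1), ]
    d2 <- rowSums(sweep(obs, 2, centers[1, ])^2)
    for (j in seq_len(k - 1) + 1) {
      # D^2 sampling; if all remaining distances are 0, fall back to uniform
      prob <- if (sum(d2) > 0) d2 else rep(1, n)
      centers[j, ] <- obs[sample.int(n, 1, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(obs, 2, centers[j, ])^2))
    }
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(obs, centers = centers,
                                     iter.max = iter.max)),
      error = function(e) {
        stats::kmeans(obs, centers = centers, iter.max = iter.max,
                      algorithm = "Lloyd")
      }
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Over-imputation (false-signal) evaluation by percentile binarization
#'
#' Binarizes the imputed matrix at the given percentile of all imputed
#' entries (an entry is called non-zero when strictly greater than the
#' threshold) and scores the calls against the true counts: positives are
#' entries with a positive true count, FPR is computed over true-zero
#' entries, and the F-score is the harmonic mean of precision and recall on
#' the positive class.
#'
#' @param imputed imputed matrix.
#' @param true_counts matching true count matrix (simulation ground truth).
#' @param percentile binarization percentile in `[0, 100]`.
#' @return named list `fpr`, `fscore`, `threshold`.
#' @export
false_signal_eval <- function(imputed, true_counts, percentile) {
  vi <- get_values(imputed)
  vt <- get_values(true_counts)
  if (!all(dim(vi) == dim(vt))) stop("shape mismatch", call. = FALSE)
  if (percentile < 0 || percentile > 100) {
    stop("`percentile` must be in [0, 100]", call. = FALSE)
  }
  pos <- vt > 0
  if (!any(!pos)) {
    stop("no true zeros: FPR undefined (use simulated data)", call. = FALSE)
  }
  thr <- stats::quantile(vi, percentile / 100, names = FALSE)
  pred <- vi > thr
  fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos)
  tp <- sum(pred & pos)
  fn <- sum(!pred & pos)
  fpr <- fp / (fp + tn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  fscore <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(fpr = fpr, fscore = fscore, threshold = thr)
}

#' False-signal curves over a grid of percentiles
#'
#' @inheritParams false_signal_eval
#' @param percentiles vector of percentiles.
#' @return data.frame with columns `percentile`, `fpr`, `fscore`.
#' @export
false_signal_curve <- function(imputed, true_counts,
                               percentiles = seq(0, 100, by = 10)) {
  rows <- lapply(percentiles, function(p) {
    r <- false_signal_eval(imputed, true_counts, p)
    data.frame(percentile = p, fpr = r$fpr, fscore = r$fscore)
  })
  do.call(rbind, rows)
}

#' Sweep the latent dimension k and score clustering recovery
#'
#' For each requested `k`: preprocess the observed counts, fit the robust
#' NMF model, impute in full mode, cluster the cells and score ARI/NMI
#' against the simulation's true group labels. The preprocessing and
#' similarity graphs do not depend on `k` and are computed once. A raw
#' baseline (clustering of the un-imputed log-normalized matrix under the
#' same protocol) is attached as the `"baseline"` attribute.
#'
#' @param sim a `SimTruth` from [simulate_groups()].
#' @param k_values integer vector of latent dimensions to try.
#' @param sigma,alpha,beta,lam model hyperparameters shared across the
#'   sweep.
#' @param seed seed for factor initialization and K-means restarts.
#' @param min_cells,hvg_n preprocessing knobs.
#' @param max_iter,tol fit settings.
#' @return data.frame with one row per requested `k`: columns `k`, `ari`,
#'   `nmi`, `status` (`"ok"` or the error message). Failed fits leave NA
#'   scores and the sweep continues.
#' @export
k_sweep <- function(sim, k_values, sigma = 1, alpha = 0.1, beta = 0.1,
                    lam = 0.1, seed = 1, min_cells = 3, hvg_n = 2000,
                    max_iter = 300, tol = 1e-4) {
  stopifnot(inherits(sim, "SimTruth"))
  proc <- preprocess_counts(count_matrix(sim$observed_counts),
                            min_cells = min_cells, hvg_n = hvg_n)
  labels <- sim$group_labels[match(proc$cell_ids,
                                   colnames(sim$observed_counts))]
  graphs <- build_graphs(proc)
  n_groups <- length(unique(sim$group_labels))
  base <- cluster_and_score(proc, labels, n_clusters = n_groups,
                            seed = seed)
  rows <- lapply(k_values, function(k) {
    tryCatch({
      hp <- hyperparams(k = k, sigma = sigma, alpha = alpha, beta = beta,
                        lam = lam)
      fit <- rnmf_fit(proc, graphs = graphs, hyper = hp, init_seed = seed,
                      max_iter = max_iter, tol = tol)
      imp <- rnmf_impute(fit)
      sc <- cluster_and_score(imp, labels, n_clusters = n_groups,
                              seed = seed)
      data.frame(k = k, ari = sc$ari, nmi = sc$nmi, status = "ok",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(k = k, ari = NA_real_, nmi = NA_real_,
                 status = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- c(ari = base$ari, nmi = base$nmi)
  out
}
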