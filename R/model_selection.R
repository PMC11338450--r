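#' Define the random hyperparameter search space
#'
#' Defaults follow the published grids: latent dimension from
#' `{2, 10, 20, 30, 40, 50}`, window width sigma on a decade grid from 1e-5
#' to 1e3, and the three regularization weights on decade grids from 1e-5 to
#' 10.
#'
#' @param k_choices candidate latent dimensions.
#' @param sigma_grid candidate window widths.
#' @param alpha_grid,beta_grid,lam_grid candidate regularizer weights.
#' @param n_samples number of configurations to draw (default 1000; scale
#'   down for quick runs).
#' @param seed RNG seed for sampling configurations.
#' @return an object of class `SearchSpace`.
#' @export
search_space <- function(k_choices = c(2, 10, 20, 30, 40, 50),
                         sigma_grid = 10^(-5:3),
                         alpha_grid = 10^(-5:1),
                         beta_grid = 10^(-5:1),
                         lam_grid = 10^(-5:1),
                         n_samples = 1000,
                         seed = 1) {
  grids <- list(k = k_choices, sigma = sigma_grid, alpha = alpha_grid,
                beta = beta_grid, lam = lam_grid)
  if (any(vapply(grids, length, 1L) == 0)) {
    stop("all grids must be non-empty", call. = FALSE)
  }
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  structure(c(grids, list(n_samples = as.integer(n_samples),
                          seed = as.integer(seed))),
            class = "SearchSpace")
}

#' Mask a fraction of the non-zero entries
#'
#' Sets `round(fraction * nnz)` uniformly chosen non-zero entries to zero and
#' records their positions and original values, so imputation accuracy can be
#' scored on held-out observed entries.
#'
#' @param x a [processed_matrix()] or bare matrix with at least one non-zero
#'   entry.
#' @param fraction fraction of non-zero entries to hide, in (0, 1).
#' @param seed RNG seed; the same seed reproduces the same mask.
#' @return list with `masked` (same class as `x`, masked entries zeroed) and
#'   `mask` (list of `index` linear positions and held-out `values`).
#' @export
mask_nonzeros <- function(x, fraction = 0.1, seed = 1) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  }
  v <- get_values(x)
  nz <- which(v != 0)
  if (length(nz) == 0) stop("matrix has no non-zero entries", call. = FALSE)
  n_mask <- max(1L, round(fraction * length(nz)))
  idx <- withr::with_seed(seed, sample(nz, n_mask))
  idx <- sort(idx)
  held <- v[idx]
  v[idx] <- 0
  masked <- if (inherits(x, "ProcessedMatrix")) {
    processed_matrix(v, x$gene_ids, x$cell_ids, x$provenance)
  } else if (inherits(x, "CountMatrix")) {
    count_matrix(v, x$gene_ids, x$cell_ids)
  } else {
    v
  }
  list(masked = masked, mask = list(index = idx, values = held))
}

#' RMSE on held-out masked entries
#'
#' @param imputed imputed matrix (same shape as the masked matrix).
#' @param mask the `mask` element returned by [mask_nonzeros()].
#' @return `sqrt(mean((imputed[mask] - heldout)^2))`.
#' @export
masked_rmse <- function(imputed, mask) {
  v <- get_values(imputed)
  if (length(mask$index) == 0) stop("empty mask", call. = FALSE)
  if (max(mask$index) > length(v)) {
    stop("mask position out of bounds", call. = FALSE)
  }
  sqrt(mean((v[mask$index] - mask$values)^2))
}

#' Random hyperparameter search by masked-entry reconstruction error
#'
#' Hides 10% of the non-zero entries once, then draws `n_samples`
#' configurations from the grids (distinct configurations when the space is
#' large enough), fits the model on the masked matrix for each, and scores
#' the RMSE between imputed and held-out values. The configuration with the
#' lowest reconstruction error wins; ties go to the earlier sample. A fit
#' that fails is scored `Inf` and the search continues. The single shared
#' mask keeps scores comparable across configurations.
#'
#' @param x a [processed_matrix()].
#' @param graphs optional [build_graphs()] result for the masked matrix;
#'   computed from the masked matrix when not supplied.
#' @param space a [search_space()].
#' @param fraction fraction of non-zeros to mask (default 0.1).
#' @param max_iter,tol fit settings passed to [rnmf_fit()].
#' @param loss loss passed to [rnmf_fit()].
#' @return list with `best` (a [hyperparams()]), `best_rmse`, `leaderboard`
#'   (data.frame of all sampled configs with scores, in sample order) and
#'   `mask`.
#' @export
random_search <- function(x, graphs = NULL, space = search_space(),
                          fraction = 0.1, max_iter = 100, tol = 1e-4,
                          loss = "closs") {
  stopifnot(inherits(space, "SearchSpace"))
  mk <- mask_nonzeros(x, fraction = fraction, seed = space$seed)
  if (is.null(graphs)) graphs <- build_graphs(mk$masked)

  configs <- draw_configs(space)
  rmse <- vapply(seq_len(nrow(configs)), function(i) {
    hp <- hyperparams(k = configs$k[i], sigma = configs$sigma[i],
                      alpha = configs$alpha[i], beta = configs$beta[i],
                      lam = configs$lam[i])
    tryCatch({
      fit <- rnmf_fit(mk$masked, graphs = graphs, hyper = hp,
                      init_seed = space$seed, max_iter = max_iter,
                      tol = tol, loss = loss)
      masked_rmse(rnmf_impute(fit), mk$mask)
    }, error = function(e) {
      warning(sprintf("config %d failed: %s", i, conditionMessage(e)),
              call. = FALSE)
      Inf
    })
  }, numeric(1))

  leaderboard <- cbind(sample = seq_len(nrow(configs)), configs,
                       rmse = rmse)
  best_i <- which.min(rmse) # first minimum: earlier sample wins ties
  best <- hyperparams(k = configs$k[best_i], sigma = configs$sigma[best_i],
                      alpha = configs$alpha[best_i],
                      beta = configs$beta[best_i],
                      lam = configs$lam[best_i])
  list(best = best, best_rmse = rmse[best_i], leaderboard = leaderboard,
       mask = mk$mask)
}

# draw n_samples configurations; distinct combinations when the full grid is
# large enough, with replacement otherwise
draw_configs <- function(space) {
  sizes <- vapply(space[c("k", "sigma", "alpha", "beta", "lam")],
                  length, 1L)
  total <- prod(sizes)
  n <- space$n_samples
  codes <- withr::with_seed(space$seed, {
    if (total >= n) sample.int(total, n) else
      sample.int(total, n, replace = TRUE)
  })
  codes <- codes - 1L
  out <- data.frame(k = numeric(n), sigma = numeric(n), alpha = numeric(n),
                    beta = numeric(n), lam = numeric(n))
  for (nm in c("k", "sigma", "alpha", "beta", "lam")) {
    g <- space[[nm]]
    out[[nm]] <- g[(codes %% length(g)) + 1L]
    codes <- codes %/% length(g)
  }
  out
}
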