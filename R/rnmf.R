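#' Hyperparameters of the robust NMF model
#'
#' @param k latent dimension (>= 1).
#' @param sigma window width of the correntropy-induced loss (> 0). Small
#'   sigma saturates the loss quickly, so large residuals at zero entries are
#'   barely penalized; large sigma approaches a quadratic loss.
#' @param alpha weight of the gene-graph regularizer `||K_G - W W'||_F^2`.
#' @param beta weight of the cell-graph regularizer `||K_C - H' H||_F^2`.
#' @param lam weight of the zero-shrinkage penalty `sum_zeros (WH)^2`.
#' @return an object of class `Hyperparams`.
#' @export
hyperparams <- function(k = 20, sigma = 1, alpha = 0.1, beta = 0.1,
                        lam = 0.1) {
  if (!is.numeric(k) || k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("`sigma` must be > 0", call. = FALSE)
  }
  if (alpha < 0 || beta < 0 || lam < 0) {
    stop("`alpha`, `beta`, `lam` must be >= 0", call. = FALSE)
  }
  structure(list(k = as.integer(k), sigma = sigma, alpha = alpha,
                 beta = beta, lam = lam),
            class = "Hyperparams")
}

#' @export
print.Hyperparams <- function(x, ...) {
  cat(sprintf("Hyperparams: k=%d sigma=%g alpha=%g beta=%g lambda=%g\n",
              x$k, x$sigma, x$alpha, x$beta, x$lam))
  invisible(x)
}

#' Correntropy-induced loss
#'
#' `closs(r, sigma) = 1 - exp(-r^2 / (2 sigma^2))`: even in the residual,
#' strictly increasing in `|r|`, bounded by 1, and `~ r^2/(2 sigma^2)` for
#' small residuals, so it behaves like a quadratic loss near zero but
#' saturates for outliers.
#'
#' @param residual numeric vector or matrix of residuals.
#' @param sigma window width (> 0).
#' @return values in `[0, 1)`, same shape as `residual`.
#' @export
closs <- function(residual, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("`sigma` must be a positive scalar", call. = FALSE)
  }
  # -expm1(-u) = 1 - exp(-u) without cancellation for small residuals
  -expm1(-residual^2 / (2 * sigma^2))
}

#' Half-quadratic weights for the zero entries
#'
#' For every zero entry of `x` the auxiliary variable of the half-quadratic
#' expansion has the closed form `L_gc = -exp(-(x_gc - (WH)_gc)^2 /
#' (2 sigma^2))`; the solver uses the weight `M = -L` on zeros and `M = 1`
#' on observed (non-zero) entries. `P` marks the zero entries (the support of
#' the robust loss and of the lambda penalty).
#'
#' @param x matrix (or [processed_matrix()]), genes x cells.
#' @param W,H current factors (genes x k, k x cells).
#' @param sigma window width (> 0).
#' @return list with matrices `M` (weights, in `(0, 1]` on zeros and exactly
#'   1 elsewhere) and `P` (0/1 indicator of zero entries).
#' @export
hq_weights <- function(x, W, H, sigma) {
  v <- get_values(x)
  check_factor_shapes(v, W, H)
  P <- (v == 0) * 1
  M <- matrix(1, nrow(v), ncol(v))
  if (any(P == 1)) {
    idx <- P == 1
    r <- v[idx] - (W %*% H)[idx]
    M[idx] <- exp(-r^2 / (2 * sigma^2))
  }
  list(M = M, P = P)
}

#' Evaluate the full objective function
#'
#' The objective is the five-term sum
#' `1/2 sum_nonzero (x - WH)^2 + 1/2 sum_zero closs(x - WH, sigma)
#'  + alpha/2 ||K_G - WW'||_F^2 + beta/2 ||K_C - H'H||_F^2
#'  + lambda/2 sum_zero (WH)^2`.
#' With `loss = "l2"` the robust term is replaced by a plain quadratic loss
#' on the zero entries (the ablation model).
#'
#' @param x matrix or [processed_matrix()].
#' @param W,H factors.
#' @param graphs a [build_graphs()] result; may be `NULL` when
#'   `alpha = beta = 0`.
#' @param hyper a [hyperparams()] object.
#' @param loss `"closs"` (default) or `"l2"`.
#' @return scalar objective value.
#' @export
rnmf_objective <- function(x, W, H, graphs = NULL, hyper = hyperparams(),
                           loss = c("closs", "l2")) {
  loss <- match.arg(loss)
  v <- get_values(x)
  check_factor_shapes(v, W, H)
  if ((hyper$alpha > 0 || hyper$beta > 0) && is.null(graphs)) {
    stop("graphs required when alpha > 0 or beta > 0", call. = FALSE)
  }
  obj_data_part(v, W, H, hyper, loss) +
    obj_graph_W(W, graphs, hyper) +
    obj_graph_H(H, graphs, hyper)
}

#' One multiplicative update of both factors
#'
#' Rescales each factor entry by a ratio of non-negative terms, W first and
#' then H using the updated W:
#' \preformatted{
#' W <- W * [ (Q*X) H' + 2 alpha K_G W ] /
#'          [ (Q*(WH)) H' + lambda (P*(WH)) H' + 2 alpha W W'W ]
#' H <- H * [ W'(Q*X) + 2 beta H K_C ] /
#'          [ W'(Q*(WH)) + lambda W'(P*(WH)) + 2 beta H H'H ]
#' }
#' Here `Q` is the effective half-quadratic weight: 1 on observed (non-zero)
#' entries and `M / (2 sigma^2)` on zero entries, which is the tangent
#' majorizer of the correntropy loss at the current residual (the numerator
#' and denominator are then the negative and positive parts of the objective
#' gradient, so fixed points are exactly the stationary points of
#' [rnmf_objective()]). Denominators are floored at `eps` and factor entries
#' are kept >= `eps` so the multiplicative scheme cannot get stuck at exact
#' zero.
#'
#' @param x matrix or [processed_matrix()].
#' @param W,H strictly positive factors.
#' @param hq half-quadratic state from [hq_weights()].
#' @param graphs [build_graphs()] result; may be `NULL` when
#'   `alpha = beta = 0`.
#' @param hyper a [hyperparams()] object.
#' @param eps denominator/entry floor.
#' @return list with updated `W` and `H`.
#' @export
update_factors <- function(x, W, H, hq, graphs = NULL, hyper = hyperparams(),
                           eps = 1e-12) {
  v <- get_values(x)
  check_factor_shapes(v, W, H)
  Q <- hq_effective_weights(hq, hyper)
  W <- step_factor_W(v, W, H, Q, hq$P, graphs, hyper, eps, gamma = 1)
  H <- step_factor_H(v, W, H, Q, hq$P, graphs, hyper, eps, gamma = 1)
  list(W = W, H = H)
}

# effective quadratic weights of the half-quadratic surrogate: 1 on observed
# entries, M/(2 sigma^2) on zeros (tangent majorizer of the C-loss). With
# loss = "l2" callers pass M = 1 and the weight on zeros is 1 as well.
hq_effective_weights <- function(hq, hyper, l2 = FALSE) {
  if (l2) return(hq$M)
  z <- hq$P == 1
  Q <- hq$M
  Q[z] <- Q[z] / (2 * hyper$sigma^2)
  Q
}

# one damped multiplicative half-step for W: W * ratio^gamma
step_factor_W <- function(v, W, H, Q, P, graphs, hyper, eps, gamma) {
  R <- W %*% H
  num <- (Q * v) %*% t(H)
  den <- (Q * R) %*% t(H)
  if (hyper$lam > 0) den <- den + hyper$lam * ((P * R) %*% t(H))
  if (hyper$alpha > 0) {
    num <- num + 2 * hyper$alpha * (graphs$K_G %*% W)
    den <- den + 2 * hyper$alpha * (W %*% crossprod(W))
  }
  ratio <- num / pmax(den, eps)
  if (gamma != 1) ratio <- ratio^gamma
  W <- pmax(W * ratio, eps)
  if (any(!is.finite(W))) stop("non-finite value in factor W", call. = FALSE)
  W
}

# one damped multiplicative half-step for H (uses the already-updated W)
step_factor_H <- function(v, W, H, Q, P, graphs, hyper, eps, gamma) {
  R <- W %*% H
  num <- crossprod(W, Q * v)
  den <- crossprod(W, Q * R)
  if (hyper$lam > 0) den <- den + hyper$lam * crossprod(W, P * R)
  if (hyper$beta > 0) {
    num <- num + 2 * hyper$beta * (H %*% graphs$K_C)
    den <- den + 2 * hyper$beta * (tcrossprod(H) %*% H)
  }
  ratio <- num / pmax(den, eps)
  if (gamma != 1) ratio <- ratio^gamma
  H <- pmax(H * ratio, eps)
  if (any(!is.finite(H))) stop("non-finite value in factor H", call. = FALSE)
  H
}

# objective split into independently cacheable parts: the data term (L2 on
# non-zeros + robust/quadratic loss and lambda shrinkage on zeros) and the
# two graph penalties. Summing the three equals rnmf_objective().
obj_data_part <- function(v, W, H, hyper, loss) {
  R <- v - W %*% H
  zero <- v == 0
  obj <- 0.5 * sum(R[!zero]^2)
  if (any(zero)) {
    rz <- R[zero]
    obj <- obj + if (loss == "closs") 0.5 * sum(closs(rz, hyper$sigma)) else
      0.5 * sum(rz^2)
    # on zeros WH = -residual, so the shrinkage term is lam/2 * sum(rz^2)
    if (hyper$lam > 0) obj <- obj + hyper$lam / 2 * sum(rz^2)
  }
  obj
}

obj_graph_W <- function(W, graphs, hyper) {
  if (hyper$alpha == 0) 0 else
    hyper$alpha / 2 * sum((graphs$K_G - tcrossprod(W))^2)
}

obj_graph_H <- function(H, graphs, hyper) {
  if (hyper$beta == 0) 0 else
    hyper$beta / 2 * sum((graphs$K_C - crossprod(H))^2)
}

# backtracking wrapper: try the full multiplicative step (gamma = 1); if the
# objective increases, halve the exponent along the same multiplicative
# direction (a provable descent direction) until it no longer does. The
# safeguard is inactive wherever the plain rule already descends, which
# includes the classical weighted-NMF regime. Only the objective parts that
# depend on the stepped factor are recomputed; `fixed` carries the rest.
safeguarded_step <- function(step_fun, v, W, H, Q, P, graphs, hyper, eps,
                             loss, fixed, obj_ref, which = c("W", "H")) {
  which <- match.arg(which)
  gamma <- 1
  slack <- 1e-12 * max(1, obj_ref)
  for (try in seq_len(25)) {
    cand <- step_fun(v, W, H, Q, P, graphs, hyper, eps, gamma)
    graph_part <- if (which == "W") obj_graph_W(cand, graphs, hyper) else
      obj_graph_H(cand, graphs, hyper)
    data_part <- if (which == "W") {
      obj_data_part(v, cand, H, hyper, loss)
    } else {
      obj_data_part(v, W, cand, hyper, loss)
    }
    obj <- data_part + graph_part + fixed
    if (obj <= obj_ref + slack) {
      return(list(factor = cand, obj = obj, graph_part = graph_part))
    }
    gamma <- gamma / 2
  }
  # no damping achieved descent (flat/stationary up to rounding): keep as is
  grp <- if (which == "W") obj_graph_W(W, graphs, hyper) else
    obj_graph_H(H, graphs, hyper)
  list(factor = if (which == "W") W else H, obj = obj_ref, graph_part = grp)
}

#' Fit the robust graph-regularized NMF model
#'
#' Alternates two stages per outer iteration: (1) the closed-form
#' half-quadratic weight update on zero entries ([hq_weights()]), and (2) one
#' multiplicative update of W then H ([update_factors()]). Stops when the
#' relative change of the objective falls below `tol` or after `max_iter`
#' iterations. Identical seed and inputs give bit-identical output.
#'
#' @param x a [processed_matrix()] (or bare non-negative matrix).
#' @param graphs optional [build_graphs()] result; built from `x` when needed
#'   (`alpha > 0` or `beta > 0`) and not supplied.
#' @param hyper a [hyperparams()] object.
#' @param init_seed RNG seed for the uniform factor initialization.
#' @param max_iter maximum number of outer iterations (>= 1).
#' @param tol relative objective-change convergence threshold.
#' @param loss `"closs"` (robust model, default) or `"l2"` (quadratic
#'   ablation on zeros: all half-quadratic weights fixed at 1).
#' @param eps numerical floor for denominators and factor entries.
#' @return an object of class `FactorModel`: fields `W`, `H`, `hyper`,
#'   `loss`, `objective_trace`, `n_iter`, `converged`, `gene_ids`,
#'   `cell_ids`, `init_seed`.
#' @export
rnmf_fit <- function(x, graphs = NULL, hyper = hyperparams(),
                     init_seed = 1, max_iter = 500, tol = 1e-4,
                     loss = c("closs", "l2"), eps = 1e-12) {
  loss <- match.arg(loss)
  v <- get_values(x)
  if (any(v < 0) || any(!is.finite(v))) {
    stop("input matrix must be non-negative and finite", call. = FALSE)
  }
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  if ((hyper$alpha > 0 || hyper$beta > 0) && is.null(graphs)) {
    graphs <- build_graphs(v)
  }
  G <- nrow(v)
  C <- ncol(v)
  k <- hyper$k
  scale <- sqrt(mean(v) / k)
  if (scale == 0) scale <- 1 # all-zero input: arbitrary positive init
  init <- withr::with_seed(init_seed, list(
    W = matrix(stats::runif(G * k), G, k) * scale,
    H = matrix(stats::runif(k * C), k, C) * scale
  ))
  W <- pmax(init$W, eps)
  H <- pmax(init$H, eps)

  trace <- numeric(max_iter)
  converged <- FALSE
  n_iter <- 0
  ones_hq <- list(M = matrix(1, G, C), P = (v == 0) * 1)
  gW <- obj_graph_W(W, graphs, hyper)
  gH <- obj_graph_H(H, graphs, hyper)
  obj_prev <- obj_data_part(v, W, H, hyper, loss) + gW + gH
  for (it in seq_len(max_iter)) {
    hq <- if (loss == "closs") {
      hq_weights(v, W, H, hyper$sigma)
    } else {
      ones_hq
    }
    Q <- hq_effective_weights(hq, hyper, l2 = (loss == "l2"))
    sw <- safeguarded_step(step_factor_W, v, W, H, Q, hq$P, graphs, hyper,
                           eps, loss, fixed = gH, obj_ref = obj_prev,
                           which = "W")
    W <- sw$factor
    gW <- sw$graph_part
    sh <- safeguarded_step(step_factor_H, v, W, H, Q, hq$P, graphs, hyper,
                           eps, loss, fixed = gW, obj_ref = sw$obj,
                           which = "H")
    H <- sh$factor
    gH <- sh$graph_part
    obj <- sh$obj
    trace[it] <- obj
    n_iter <- it
    if (it > 1 && abs(obj_prev - obj) / max(obj_prev, eps) < tol) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }

  structure(
    list(W = W, H = H, hyper = hyper, loss = loss,
         objective_trace = trace[seq_len(n_iter)],
         n_iter = n_iter, converged = converged,
         gene_ids = rownames(v), cell_ids = colnames(v),
         init_seed = init_seed),
    class = "FactorModel"
  )
}

#' @export
print.FactorModel <- function(x, ...) {
  cat(sprintf(
    "FactorModel: %d genes x %d cells, k=%d, loss=%s, %d iterations%s\n",
    nrow(x$W), ncol(x$H), x$hyper$k, x$loss, x$n_iter,
    if (x$converged) " (converged)" else ""
  ))
  cat(sprintf("  final objective: %.6g\n",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Reconstruct the expression matrix from a fitted model
#'
#' `mode = "full"` returns the factor product `WH` everywhere (the imputed
#' matrix used for downstream analysis); `mode = "zeros_only"` keeps observed
#' non-zero entries at their input values and substitutes `WH` only at zeros.
#'
#' @param model a fitted `FactorModel`.
#' @param x the matrix the model was fitted on; required for
#'   `mode = "zeros_only"`.
#' @param mode `"full"` (default) or `"zeros_only"`.
#' @return non-negative genes x cells matrix.
#' @export
rnmf_impute <- function(model, x = NULL, mode = c("full", "zeros_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "FactorModel"))
  xhat <- model$W %*% model$H
  if (!is.null(model$gene_ids)) {
    dimnames(xhat) <- list(model$gene_ids, model$cell_ids)
  }
  if (mode == "zeros_only") {
    if (is.null(x)) stop("`x` is required for mode = \"zeros_only\"",
                         call. = FALSE)
    v <- get_values(x)
    if (!all(dim(v) == dim(xhat))) {
      stop("shape mismatch between model and `x`", call. = FALSE)
    }
    keep <- v != 0
    xhat[keep] <- v[keep]
  }
  xhat
}

#' Save / load a fitted model as a plain-text bundle
#'
#' Writes `W.csv`, `H.csv`, the objective trace and a flat key-value file of
#' hyperparameters into `dir`.
#'
#' @param model a `FactorModel`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(model$W, file.path(dir, "W.csv"), row.names = FALSE)
  utils::write.csv(model$H, file.path(dir, "H.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(iteration = seq_along(model$objective_trace),
               objective = model$objective_trace),
    file.path(dir, "objective_trace.csv"), row.names = FALSE
  )
  write_flat_config(
    c(unclass(model$hyper),
      list(loss = model$loss, n_iter = model$n_iter,
           converged = model$converged, init_seed = model$init_seed)),
    file.path(dir, "model.txt")
  )
  invisible(dir)
}

check_factor_shapes <- function(v, W, H) {
  if (!is.matrix(W) || !is.matrix(H)) {
    stop("W and H must be matrices", call. = FALSE)
  }
  if (nrow(W) != nrow(v) || ncol(H) != ncol(v) || ncol(W) != nrow(H)) {
    stop(sprintf(
      "shape mismatch: x is %dx%d, W is %dx%d, H is %dx%d",
      nrow(v), ncol(v), nrow(W), ncol(W), nrow(H), ncol(H)
    ), call. = FALSE)
  }
  invisible(TRUE)
}
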