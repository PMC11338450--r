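test_that("closs matches its closed form and bounds", {
  expect_identical(closs(0, 1), 0)
  expect_equal(closs(1, 1), 1 - exp(-0.5), tolerance = 1e-12)
  expect_equal(closs(2.5, 2.5), 1 - exp(-0.5), tolerance = 1e-12)
  r <- seq(-10, 10, by = 0.25)
  expect_equal(closs(r, 0.7), closs(-r, 0.7))          # even
  expect_true(all(closs(r, 0.7) <= 1))                 # bounded
  expect_true(all(closs(r[abs(r) <= 3], 0.7) < 1))     # strict inside
  expect_true(all(diff(closs(r[r >= 0], 0.7)) >= 0))   # increasing in |r|
  # quadratic bound with ratio -> 1 as r -> 0
  pos <- r[r > 0]
  expect_true(all(closs(pos, 1.3) <= pos^2 / (2 * 1.3^2) + 1e-15))
  expect_equal(closs(1e-6, 1.3) / (1e-12 / (2 * 1.3^2)), 1, tolerance = 1e-9)
  expect_error(closs(1, 0), "positive")
  expect_error(closs(1, -2), "positive")
})

test_that("hq_weights gives M = -L on zeros and 1 elsewhere", {
  x <- matrix(c(1, 0, 0, 2), 2)
  W <- matrix(c(1, 1), 2, 1)
  H <- matrix(c(1, 1), 1, 2)
  hq <- hq_weights(x, W, H, sigma = 1)
  expect_equal(hq$P, (x == 0) * 1)
  # non-zero entries: exactly 1 regardless of residual
  expect_identical(hq$M[x != 0], c(1, 1))
  # zero entries with residual 0 - 1 = -1, sigma 1 -> exp(-1/2)
  expect_equal(hq$M[x == 0], rep(exp(-0.5), 2), tolerance = 1e-12)
  # residual = sigma gives exp(-1/2) for any sigma
  x2 <- matrix(0, 1, 1)
  hq2 <- hq_weights(x2, matrix(3), matrix(1), sigma = 3)
  expect_equal(hq2$M[1, 1], exp(-0.5), tolerance = 1e-12)
  # zero residual on a zero entry
  hq3 <- hq_weights(x2, matrix(0), matrix(1), sigma = 2)
  expect_equal(hq3$M[1, 1], 1)
})

test_that("objective matches hand computation and scalar-loop oracle", {
  # 2x2 worked case: L2 on non-zeros + C-loss on zeros + lambda on zeros
  x <- matrix(c(1, 0, 0, 2), 2, byrow = TRUE)
  W <- matrix(c(1, 1), 2, 1)
  H <- matrix(c(1, 1), 1, 2)
  hp <- hyperparams(k = 1, sigma = 1, alpha = 0, beta = 0, lam = 1)
  expect_equal(rnmf_objective(x, W, H, hyper = hp),
               0.5 + (1 - exp(-0.5)) + 1.0, tolerance = 1e-12)
  # all-zero input with zero factors
  z <- matrix(0, 2, 2)
  hp0 <- hyperparams(k = 1, sigma = 1, alpha = 0, beta = 0, lam = 0)
  expect_equal(rnmf_objective(z, matrix(0, 2, 1), matrix(0, 1, 2),
                              hyper = hp0), 0)
  # no zeros + perfect fit
  expect_equal(rnmf_objective(W %*% H, W, H, hyper = hp0), 0)
  # random case incl. graph terms against the independent scalar-loop oracle
  lk <- withr::with_seed(21, {
    v <- matrix(rpois(6 * 5, 1.5), 6, 5)
    list(v = v, W = matrix(runif(6 * 2), 6, 2),
         H = matrix(runif(2 * 5), 2, 5))
  })
  g <- build_graphs(lk$v)
  hp2 <- hyperparams(k = 2, sigma = 0.8, alpha = 0.3, beta = 0.7, lam = 0.2)
  expect_equal(
    rnmf_objective(lk$v, lk$W, lk$H, g, hp2),
    oracle_objective(lk$v, lk$W, lk$H, g$K_G, g$K_C,
                     sigma = 0.8, alpha = 0.3, beta = 0.7, lam = 0.2),
    tolerance = 1e-10
  )
  expect_error(rnmf_objective(lk$v, lk$W[1:3, ], lk$H, g, hp2), "mismatch")
})

test_that("update_factors: fixed point at exact fit, non-negative outputs", {
  lr <- positive_lowrank(8, 6, 2, seed = 31)
  hq <- hq_weights(lr$X, lr$W, lr$H, 1)
  hp <- hyperparams(k = 2, sigma = 1, alpha = 0, beta = 0, lam = 0)
  upd <- update_factors(lr$X, lr$W, lr$H, hq, hyper = hp)
  expect_equal(upd$W, lr$W, tolerance = 1e-12)
  expect_equal(upd$H, lr$H, tolerance = 1e-12)
  # arbitrary valid input stays non-negative
  lk <- withr::with_seed(32, {
    v <- matrix(rpois(40, 1), 8, 5)
    list(v = v, W = matrix(runif(16, 0.1, 1), 8, 2),
         H = matrix(runif(10, 0.1, 1), 2, 5))
  })
  g <- build_graphs(lk$v)
  hp2 <- hyperparams(k = 2, sigma = 0.5, alpha = 0.2, beta = 0.2, lam = 0.3)
  hq2 <- hq_weights(lk$v, lk$W, lk$H, 0.5)
  upd2 <- update_factors(lk$v, lk$W, lk$H, hq2, g, hp2)
  expect_true(all(upd2$W >= 0) && all(upd2$H >= 0))
})

test_that("update equals the classical multiplicative NMF step when all
           weights are 1 (no zeros, no regularizers)", {
  lk <- withr::with_seed(33, {
    list(X = matrix(runif(30, 0.2, 3), 6, 5),
         W = matrix(runif(12, 0.1, 1), 6, 2),
         H = matrix(runif(10, 0.1, 1), 2, 5))
  })
  hp <- hyperparams(k = 2, sigma = 1, alpha = 0, beta = 0, lam = 0)
  hq <- hq_weights(lk$X, lk$W, lk$H, 1)
  upd <- update_factors(lk$X, lk$W, lk$H, hq, hyper = hp)
  oracle <- oracle_nmf_step(lk$X, lk$W, lk$H)
  expect_equal(upd$W, oracle$W, tolerance = 1e-12)
  expect_equal(upd$H, oracle$H, tolerance = 1e-12)
})

test_that("fit recovers an exact low-rank factorization", {
  lr <- positive_lowrank(30, 20, 2, seed = 12)
  hp <- hyperparams(k = 2, sigma = 1, alpha = 0, beta = 0, lam = 0)
  fit <- rnmf_fit(lr$X, hyper = hp, init_seed = 7, max_iter = 5000,
                  tol = 1e-12)
  rel <- norm(lr$X - fit$W %*% fit$H, "F") / norm(lr$X, "F")
  expect_lt(rel, 1e-3)
})

test_that("fit matches an independent plain-NMF path per iteration in the
           degenerate regime", {
  lr <- positive_lowrank(30, 20, 3, seed = 44)
  X <- lr$X # strictly positive, no zeros
  hp <- hyperparams(k = 3, sigma = 1, alpha = 0, beta = 0, lam = 0)
  scale <- sqrt(mean(X) / 3)
  ini <- withr::with_seed(9, list(
    W = pmax(matrix(runif(30 * 3), 30, 3) * scale, 1e-12),
    H = pmax(matrix(runif(3 * 20), 3, 20) * scale, 1e-12)
  ))
  W <- ini$W
  H <- ini$H
  for (it in 1:50) {
    st <- oracle_nmf_step(X, W, H)
    W <- st$W
    H <- st$H
  }
  fit <- rnmf_fit(X, hyper = hp, init_seed = 9, max_iter = 50, tol = 0)
  expect_equal(fit$W, W, tolerance = 1e-10)
  expect_equal(fit$H, H, tolerance = 1e-10)
})

test_that("fit is deterministic and records a monotone objective trace", {
  lk <- small_proc(n_genes = 80, n_cells = 40, seed = 17)
  g <- build_graphs(lk$proc)
  hp <- hyperparams(k = 4, sigma = 1, alpha = 0.1, beta = 0.1, lam = 0.1)
  f1 <- rnmf_fit(lk$proc, graphs = g, hyper = hp, init_seed = 3,
                 max_iter = 60, tol = 0)
  f2 <- rnmf_fit(lk$proc, graphs = g, hyper = hp, init_seed = 3,
                 max_iter = 60, tol = 0)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_true(is_nonincreasing(f1$objective_trace))
  expect_true(all(f1$W >= 0) && all(f1$H >= 0))
})

test_that("permuting genes permutes W rows and preserves the objective", {
  lk <- small_proc(n_genes = 60, n_cells = 30, seed = 23)
  v <- lk$proc$values
  g <- build_graphs(v)
  hp <- hyperparams(k = 3, sigma = 1, alpha = 0.2, beta = 0.2, lam = 0.1)
  fit <- rnmf_fit(v, graphs = g, hyper = hp, init_seed = 2, max_iter = 30,
                  tol = 0)
  perm <- withr::with_seed(4, sample(nrow(v)))
  gp <- list(K_G = g$K_G[perm, perm], K_C = g$K_C)
  obj <- rnmf_objective(v, fit$W, fit$H, g, hp)
  obj_p <- rnmf_objective(v[perm, ], fit$W[perm, ], fit$H, gp, hp)
  expect_equal(obj, obj_p, tolerance = 1e-10)
})

test_that("impute modes behave per contract", {
  lk <- small_proc(n_genes = 50, n_cells = 25, seed = 29)
  hp <- hyperparams(k = 3, sigma = 1, alpha = 0, beta = 0, lam = 0.1)
  fit <- rnmf_fit(lk$proc, hyper = hp, init_seed = 1, max_iter = 40)
  full <- rnmf_impute(fit, mode = "full")
  expect_true(all(full >= 0))
  zo <- rnmf_impute(fit, x = lk$proc, mode = "zeros_only")
  v <- lk$proc$values
  expect_identical(zo[v != 0], v[v != 0])
  expect_identical(zo[v == 0], full[v == 0])
  expect_error(rnmf_impute(fit, mode = "zeros_only"), "required")
  # identity-like product
  m <- structure(list(W = rbind(c(1, 0), c(0, 1)),
                      H = rbind(c(2, 0), c(0, 3)),
                      gene_ids = NULL, cell_ids = NULL),
                 class = "FactorModel")
  expect_equal(rnmf_impute(m), rbind(c(2, 0), c(0, 3)))
})

test_that("fit validates arguments", {
  expect_error(rnmf_fit(matrix(1, 2, 2), hyper = hyperparams(k = 1),
                        max_iter = 0), "max_iter")
  expect_error(rnmf_fit(matrix(-1, 2, 2), hyper = hyperparams(k = 1)),
               "non-negative")
  expect_error(hyperparams(k = 0), "k")
  expect_error(hyperparams(sigma = 0), "sigma")
  expect_error(hyperparams(alpha = -1), ">= 0")
})
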