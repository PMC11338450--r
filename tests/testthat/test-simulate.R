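test_that("simulate_groups is deterministic with equal group split", {
  p <- sim_params(n_genes = 100, n_cells = 57, n_groups = 4, seed = 10)
  s1 <- simulate_groups(p)
  s2 <- simulate_groups(p)
  expect_identical(s1$true_counts, s2$true_counts)
  expect_identical(s1$observed_counts, s2$observed_counts)
  expect_identical(s1$dropout_mask, s2$dropout_mask)
  # 57 cells, 4 groups: remainder goes to the last group
  expect_equal(as.vector(table(s1$group_labels)), c(14, 14, 14, 15))
  p4 <- sim_params(n_genes = 20, n_cells = 500, n_groups = 4, seed = 1)
  expect_equal(as.vector(table(simulate_groups(p4)$group_labels)),
               rep(125L, 4))
})

test_that("observed counts respect the dropout mask", {
  s <- simulate_groups(sim_params(n_genes = 80, n_cells = 40, seed = 3,
                                  dropout_mid = 2))
  m <- s$dropout_mask == 1
  expect_true(all(s$observed_counts[m] == 0))
  expect_identical(s$observed_counts[!m], s$true_counts[!m])
  expect_true(all(s$true_counts >= 0))
  expect_true(all(s$true_counts == round(s$true_counts)))
})

test_that("extreme dropout curves give the no-dropout and all-dropout limits", {
  # dropout probability ~ 0 everywhere: shape strongly negative, mid low
  p0 <- sim_params(n_genes = 50, n_cells = 30, seed = 5,
                   dropout_mid = -100, dropout_shape = -1)
  s0 <- simulate_groups(p0)
  expect_identical(s0$observed_counts, s0$true_counts)
  expect_true(all(s0$dropout_mask == 0))
  # mid very high: everything dropped
  p1 <- sim_params(n_genes = 50, n_cells = 30, seed = 5,
                   dropout_mid = 100, dropout_shape = -1)
  expect_true(all(simulate_groups(p1)$observed_counts == 0))
})

test_that("observed zero fraction is non-decreasing in dropout_mid", {
  base <- sim_params(n_genes = 100, n_cells = 50, seed = 8)
  mids <- c(-5, 0, 2, 4, 8)
  zr <- vapply(mids, function(m) {
    p <- base
    p$dropout_mid <- m
    mean(simulate_groups(p)$observed_counts == 0)
  }, numeric(1))
  expect_true(all(diff(zr) >= 0))
})

test_that("calibrate_dropout hits the target and is monotone", {
  p <- sim_params(n_genes = 200, n_cells = 100, seed = 13)
  c70 <- calibrate_dropout(p, 0.70)
  s <- simulate_groups(c70)
  expect_gt(mean(s$observed_counts == 0), 0.67)
  expect_lt(mean(s$observed_counts == 0), 0.73)
  expect_equal(c70$achieved_zero_rate, 0.70, tolerance = 0.01)
  c85 <- calibrate_dropout(p, 0.85)
  expect_gt(c85$dropout_mid, c70$dropout_mid)
  # unachievable target below the structural floor errors with the floor
  expect_error(calibrate_dropout(p, 1e-6), "structural")
})

test_that("same-group cells correlate more than cross-group cells", {
  s <- simulate_groups(sim_params(n_genes = 200, n_cells = 60,
                                  n_groups = 3, seed = 21))
  lc <- log1p(s$true_counts)
  cc <- stats::cor(lc)
  same <- outer(s$group_labels, s$group_labels, `==`)
  diag(same) <- NA
  expect_gt(mean(cc[which(same)], na.rm = TRUE),
            mean(cc[which(!same)], na.rm = TRUE))
})

test_that("presets have the stated shapes, groups and zero rates", {
  pre <- sim_presets(c("sim1", "sim9"))
  s1 <- simulate_groups(pre$sim1)
  expect_equal(dim(s1$observed_counts), c(1000, 500))
  expect_equal(length(unique(s1$group_labels)), 4)
  expect_equal(mean(s1$observed_counts == 0), 0.78, tolerance = 0.015)
  s9 <- simulate_groups(pre$sim9)
  expect_equal(dim(s9$observed_counts), c(500, 2000))
  expect_equal(length(unique(s9$group_labels)), 20)
  expect_equal(mean(s9$observed_counts == 0), 0.90, tolerance = 0.015)
  # regeneration from the fixed preset seed is bit-identical
  expect_identical(simulate_preset("sim1")$observed_counts,
                   s1$observed_counts)
  expect_error(sim_presets("sim99"), "unknown")
})

test_that("write_sim produces a readable directory", {
  s <- simulate_groups(sim_params(n_genes = 30, n_cells = 15, seed = 2))
  d <- file.path(withr::local_tempdir(), "simout")
  write_sim(s, d, format = "mtx_dir")
  back <- read_counts(file.path(d, "observed_counts"), "mtx_dir")
  expect_equal(unname(back$values), unname(s$observed_counts))
  labs <- utils::read.csv(file.path(d, "group_labels.csv"))
  expect_equal(labs$group, s$group_labels)
  prm <- rnmfimpute:::read_flat_config(file.path(d, "params.txt"))
  expect_equal(prm$seed, 2)
})
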