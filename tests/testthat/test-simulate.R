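test_that("confounder-to-label variance ratio is rescaled exactly", {
  set.seed(50)
  for (s in c(0.1, 0.5, 0.9)) {
    cfg <- sim_config(n_individuals = 40, var_xw = s, seed = 1)
    ind <- simulate_individuals(cfg)
    a <- as.numeric(ind$X %*% ind$alpha)
    expect_lt(abs(var(a) / var(a + ind$eps_w) - s), 1e-6)
  }
})

test_that("labels are symmetric coin flips without confounding", {
  set.seed(51)
  cfg <- sim_config(n_individuals = 10000, var_xw = 0, seed = 1)
  ind <- simulate_individuals(cfg)
  expect_equal(ind$alpha, rep(0, cfg$d_c))
  expect_lt(abs(mean(ind$W) - 0.5), 0.02)
  expect_error(simulate_individuals(sim_config(n_individuals = 1)),
               "at least 2")
})

test_that("identical seeds reproduce the dataset bitwise", {
  cfg <- sim_config(n_genes = 60, n_individuals = 6,
                    cells_per_individual = 8, seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(as.matrix(s1$counts$counts), as.matrix(s2$counts$counts))
  expect_identical(s1$truth, s2$truth)
})

test_that("gene means follow the structural variance decomposition", {
  ## non-causal genes have exactly zero disease contribution
  set.seed(52)
  cfg <- sim_config(n_genes = 500, n_causal = 30, n_individuals = 20,
                    seed = 1)
  ind <- simulate_individuals(cfg)
  lam <- simulate_lambda(ind$X, ind$B, ind$W, cfg)
  expect_equal(sum(lam$causal_flags), 30L)
  expect_true(all(lam$tau[!lam$causal_flags] == 0))

  ## with no covariate or disease effect, log-means are standard normal
  cfg0 <- sim_config(n_genes = 5000, n_individuals = 20, var_wy = 0,
                     var_xby = 0, n_causal = 0, seed = 1)
  ind0 <- simulate_individuals(cfg0)
  lam0 <- simulate_lambda(ind0$X, ind0$B, ind0$W, cfg0)
  lnl <- log(lam0$lambda)
  expect_lt(abs(mean(lnl)), 0.02)
  expect_lt(abs(var(as.numeric(lnl)) - 1), 0.03)

  ## regression-based variance partition recovers the prescribed shares
  set.seed(53)
  cfgv <- sim_config(n_genes = 2000, n_causal = 2000, n_individuals = 400,
                     var_wy = 0.2, var_xby = 0.5, var_xw = 0.5, seed = 1)
  indv <- simulate_individuals(cfgv)
  lamv <- simulate_lambda(indv$X, indv$B, indv$W, cfgv)
  lnlv <- log(lamv$lambda)
  ## disease share: tau_g^2 Var(W); covariate share: Var(X beta_g)
  vw <- mean(vapply(seq_len(2000), function(g)
    var(lamv$tau[g] * indv$W), numeric(1)))
  vx <- mean(vapply(seq_len(2000), function(g)
    var(as.numeric(indv$X %*% lamv$beta[, g])), numeric(1)))
  vtot <- mean(apply(lnlv, 1L, var))
  ## tau ~ N(0, 0.2) and Var(W) ~ 1/4, so E[share_W] = 0.05 of total ~1.05
  expect_lt(abs(vw - cfgv$var_wy * 0.25), 0.02)
  expect_lt(abs(vx - cfgv$var_xby), 0.03)
  expect_lt(abs(vtot - (cfgv$var_wy * 0.25 + cfgv$var_xby +
                        (1 - cfgv$var_wy - cfgv$var_xby))), 0.05)

  expect_error(sim_config(var_wy = 0.5, var_xby = 0.6), "< 1")
})

test_that("cell counts are Poisson with Gamma depth overdispersion", {
  set.seed(54)
  cfg <- sim_config(n_genes = 1, n_individuals = 1, n_causal = 0,
                    cells_per_individual = 1e5, fixed_cells = TRUE,
                    seed = 1)
  lambda <- matrix(2, 1, 1, dimnames = list("g1", "i1"))
  cells <- simulate_cells(lambda, cfg)
  rho <- cells$rho
  expect_lt(abs(mean(rho) - 1), 0.01)
  expect_lt(abs(var(rho) - 1 / 6.25), 0.01)
  y <- as.numeric(cells$counts$counts[1, ])
  expect_lt(abs(mean(y) - 2) / 2, 0.02)
  ## law of total variance: V[Y] = lambda + lambda^2 V[rho]
  expect_lt(abs(var(y) - (2 + 4 * 0.16)) / (2 + 4 * 0.16), 0.05)
  ## every individual gets at least one cell
  cfg2 <- sim_config(n_genes = 5, n_causal = 0, n_individuals = 30,
                     cells_per_individual = 1, seed = 2)
  sim2 <- simulate_dataset(cfg2)
  expect_true(all(table(sim2$meta$cells$individual_id) >= 1))
})

test_that("simulated datasets round-trip through the disk format", {
  dir <- withr::local_tempdir()
  sim <- tiny_sim(seed = 19L)
  write_sim_dataset(sim, dir)
  counts <- read_count_matrix(file.path(dir, "matrix.mtx"),
                              file.path(dir, "genes.tsv"),
                              file.path(dir, "barcodes.tsv"))
  meta <- read_cell_meta(file.path(dir, "cells.tsv"),
                         file.path(dir, "labels.tsv"))
  expect_identical(as.matrix(counts$counts), as.matrix(sim$counts$counts))
  expect_identical(meta$labels, sim$meta$labels)
  truth <- read.delim(file.path(dir, "truth_genes.tsv"))
  expect_equal(sum(truth$causal), sum(sim$truth$causal_flags))
})
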