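## helper: wrap a matrix as counterfactual_counts
as_cf <- function(yhat) {
  structure(list(yhat = yhat, method = "poisson_reg"),
            class = "counterfactual_counts")
}

small_instance <- function(seed = 3L, n_genes = 50L) {
  sim <- tiny_sim(seed = seed, n_genes = n_genes)
  emb <- embed_cells(sim$counts, rank = 5)
  mt <- match_opposite(emb, sim$meta, k = 5)
  cf <- impute_counterfactual(sim$counts, mt)
  list(sim = sim, cf = cf)
}

test_that("confounder update reduces to identical halves when Yhat = Y", {
  sim <- tiny_sim(seed = 4L)
  y <- as.matrix(sim$counts$counts)
  fit <- estimate_confounder(sim$counts, as_cf(y), sim$meta)
  expect_true(fit$converged)
  ## with identical halves both depth blocks coincide, and at the fixed
  ## point E[mu] = (1 + 2 sum Y) / (1 + 2 sum E[rho])
  expect_equal(fit$rho_obs, fit$rho_cf, tolerance = 1e-10)
  ind <- sim$meta$cells$individual_id[match(colnames(y),
                                            sim$meta$cells$cell_id)]
  ysum <- t(rowsum(t(y), ind))
  rsum <- tapply(fit$rho_obs, ind, sum)[colnames(ysum)]
  expected <- sweep(1 + 2 * ysum, 2L, 1 + 2 * as.numeric(rsum), "/")
  expect_equal(unname(fit$mu[, colnames(ysum)]), unname(expected),
               tolerance = 1e-6)
})

test_that("confounder estimate is invariant to relabelling conditions", {
  inst <- small_instance()
  meta <- inst$sim$meta
  flipped <- meta
  flipped$labels <- stats::setNames(1L - meta$labels, names(meta$labels))
  f1 <- estimate_confounder(inst$sim$counts, inst$cf, meta)
  f2 <- estimate_confounder(inst$sim$counts, inst$cf, flipped)
  expect_identical(f1$mu, f2$mu)
})

test_that("confounder fixed point matches a brute-force oracle", {
  inst <- small_instance(seed = 8L, n_genes = 50L)
  y <- as.matrix(inst$sim$counts$counts)
  yhat <- inst$cf$yhat
  ind <- inst$sim$meta$cells$individual_id[match(colnames(y),
                                                 inst$sim$meta$cells$cell_id)]
  fit <- estimate_confounder(inst$sim$counts, inst$cf, inst$sim$meta)
  expect_true(fit$converged)
  ## naive alternating iteration run 10x longer
  inds <- sort(unique(ind))
  rho_o <- rep(1, ncol(y)); rho_c <- rep(1, ncol(y))
  mu <- matrix(1, nrow(y), length(inds))
  for (it in seq_len(10L * fit$iterations)) {
    for (ii in seq_along(inds)) {
      cells <- which(ind == inds[ii])
      mu[, ii] <- (1 + rowSums(y[, cells, drop = FALSE]) +
                     rowSums(yhat[, cells, drop = FALSE])) /
        (1 + sum(rho_o[cells]) + sum(rho_c[cells]))
    }
    mu_col <- colSums(mu)
    for (j in seq_len(ncol(y))) {
      ii <- match(ind[j], inds)
      rho_o[j] <- (1 + sum(y[, j])) / (1 + mu_col[ii])
      rho_c[j] <- (1 + sum(yhat[, j])) / (1 + mu_col[ii])
    }
  }
  ord <- match(colnames(fit$mu), inds)
  expect_lt(max(abs(fit$mu - mu[, ord]) / pmax(mu[, ord], 1e-12)), 1e-6)
})

test_that("unit confounder reduces the residual to Bayesian pseudo-bulk", {
  sim <- tiny_sim(seed = 6L)
  mu1 <- matrix(1, nrow(sim$counts$counts),
                length(unique(sim$meta$cells$individual_id)))
  colnames(mu1) <- sort(unique(sim$meta$cells$individual_id))
  rownames(mu1) <- sim$counts$gene_ids
  res <- estimate_residual(sim$counts, mu1, sim$meta)
  pb <- pseudobulk(sim$counts, sim$meta, "bayes")
  expect_equal(res$delta, pb$lambda[, colnames(res$delta)],
               tolerance = 1e-6)
})

test_that("log-scale posterior summaries follow the digamma closed form", {
  ## single individual, two cells, one read total; mu fixed at 1.
  ## hand-iterate the alternating updates as an independent oracle, then
  ## check E[ln delta] = psi(1 + sum Y) - log(1 + mu sum rho) and
  ## V[ln delta] = 1 / sum Y
  y <- matrix(c(1, 0), 1, 2)
  cc <- cell_counts(y)
  meta <- structure(list(cells = data.frame(cell_id = cc$cell_ids,
                                            individual_id = "i1"),
                         labels = c(i1 = 0L)), class = "cell_meta")
  mu <- matrix(1, 1, 1, dimnames = list("g1", "i1"))
  res <- estimate_residual(cc, mu, meta)
  rho_h <- c(1, 1)
  for (it in 1:5000) {
    delta_h <- (1 + 1) / (1 + sum(rho_h))
    rho_h <- (1 + colSums(y)) / (1 + delta_h)
  }
  expect_equal(unname(res$delta[1, 1]), delta_h, tolerance = 1e-6)
  expect_equal(res$ln_delta_mean[1, 1],
               digamma(2) - log(1 + sum(rho_h)), tolerance = 1e-6)
  expect_equal(res$ln_delta_var[1, 1], 1)
  ## when mu sum(rho) = 1 the closed form evaluates to psi(2) - ln 2,
  ## i.e. (1 - Euler's gamma) - ln 2
  expect_equal(digamma(2) - log(2), (1 - -digamma(1)) - log(2))

  ## sum Y = 4 gives V[ln delta] = 1/4; zero counts are flagged missing
  y4 <- rbind(c(2, 2), c(0, 0))  # gene 1: four reads; gene 2: none
  cc4 <- cell_counts(y4)
  meta4 <- structure(list(cells = data.frame(cell_id = cc4$cell_ids,
                                             individual_id = "i1"),
                          labels = c(i1 = 1L)), class = "cell_meta")
  mu4 <- matrix(1, 2, 1, dimnames = list(cc4$gene_ids, "i1"))
  res4 <- estimate_residual(cc4, mu4, meta4)
  expect_equal(res4$ln_delta_var[1, 1], 0.25)
  expect_true(is.na(res4$ln_delta_mean[2, 1]))
  expect_true(is.na(res4$ln_delta_var[2, 1]))
  expect_true(res4$delta[2, 1] > 0)  # E[delta] still defined
})

test_that("mu times delta reconstructs the Bayesian pseudo-bulk ranking", {
  inst <- small_instance(seed = 12L, n_genes = 120L)
  conf <- estimate_confounder(inst$sim$counts, inst$cf, inst$sim$meta)
  res <- estimate_residual(inst$sim$counts, conf$mu, inst$sim$meta)
  pb <- pseudobulk(inst$sim$counts, inst$sim$meta, "bayes")$lambda
  recon <- conf$mu * res$delta
  for (i in seq_len(ncol(pb))) {
    expect_gt(stats::cor(recon[, i], pb[, i], method = "spearman"), 0.99)
  }
})

test_that("residual estimation validates the confounder matrix", {
  sim <- tiny_sim(seed = 2L)
  mu <- matrix(1, nrow(sim$counts$counts), 6)
  mu[1, 1] <- 0
  colnames(mu) <- sort(unique(sim$meta$cells$individual_id))
  expect_error(estimate_residual(sim$counts, mu, sim$meta), "positive")
})
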