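## Shared fixtures and independent oracles used across test files.

## small simulated dataset for plumbing tests
tiny_sim <- function(seed = 42L, n_genes = 80L, n_individuals = 6L,
                     cells = 10L, ...) {
  simulate_dataset(sim_config(n_genes = n_genes, n_causal = 5L,
                              n_individuals = n_individuals,
                              cells_per_individual = cells, seed = seed,
                              ...))
}

## brute-force alternating Poisson-Gamma VB oracle, naive loops
vb_oracle <- function(y, individual, n_iter) {
  y <- as.matrix(y)
  inds <- sort(unique(individual))
  rho <- rep(1, ncol(y))
  lambda <- matrix(0, nrow(y), length(inds))
  for (it in seq_len(n_iter)) {
    for (ii in seq_along(inds)) {
      cells <- which(individual == inds[ii])
      for (g in seq_len(nrow(y)))
        lambda[g, ii] <- (sum(y[g, cells]) + 1) / (sum(rho[cells]) + 1)
    }
    for (j in seq_len(ncol(y))) {
      ii <- match(individual[j], inds)
      rho[j] <- (sum(y[, j]) + 1) / (sum(lambda[, ii]) + 1)
    }
  }
  list(lambda = lambda, rho = rho)
}

## exact two-sided rank-sum p-value by enumerating all C(n1+n2, n1)
## assignments (no ties assumed)
ranksum_enum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  w_all <- apply(combs, 2L, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

## point-by-point precision-recall curve enumeration (handles ties by
## grouping equal scores), trapezoidal area
auprc_enum <- function(scores, flags) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; f <- as.logical(flags[o])
  np <- sum(f)
  rec <- numeric(0); prec <- numeric(0)
  i <- 1L
  tp <- 0L; fp <- 0L
  while (i <= length(s)) {
    j <- i
    while (j < length(s) && s[j + 1L] == s[i]) j <- j + 1L
    tp <- tp + sum(f[i:j]); fp <- fp + sum(!f[i:j])
    rec <- c(rec, tp / np); prec <- c(prec, tp / (tp + fp))
    i <- j + 1L
  }
  rec0 <- c(0, rec); prec0 <- c(prec[1L], prec)
  sum(diff(rec0) * (prec0[-1L] + prec0[-length(prec0)]) / 2)
}
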