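#' Configuration of the confounded case-control generative model
#'
#' Study-design parameters of the simulator: a cohort of individuals whose
#' binary disease label is influenced by latent confounders \eqn{X}, gene
#' means driven by disease, confounders and batch covariates, and
#' cell-level Poisson counts with Gamma sequencing depths.
#'
#' @param n_genes number of genes (default 10,000).
#' @param n_causal number of causally disease-affected genes (default 50).
#' @param n_individuals cohort size (default 40).
#' @param cells_per_individual mean cells per individual (default 50);
#'   realised counts are Poisson around this mean with floor 1 unless
#'   `fixed_cells = TRUE`.
#' @param d_c number of confounding covariates (1-5, default 5).
#' @param d_b number of non-confounding batch covariates (0-4, default 0).
#' @param var_xw proportion of disease-label variance explained by the
#'   confounders (\eqn{\sigma^2_{X \to W}}, default 0.5).
#' @param var_wy proportion of log-mean-expression variance explained by
#'   disease on causal genes (\eqn{\sigma^2_{W \to Y}}, default 0.3).
#' @param var_xby proportion of log-mean-expression variance explained by
#'   confounders and batch jointly (\eqn{\sigma^2_{X,B \to Y}}, default 0.5).
#' @param depth_shape,depth_rate Gamma parameters of per-cell sequencing
#'   depth (default 6.25 and 6.25: mean 1, variance 0.16).
#' @param fixed_cells if `TRUE`, every individual gets exactly
#'   `cells_per_individual` cells.
#' @param seed integer RNG seed used by [simulate_dataset()].
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000L, n_causal = 50L,
                       n_individuals = 40L, cells_per_individual = 50,
                       d_c = 5L, d_b = 0L, var_xw = 0.5, var_wy = 0.3,
                       var_xby = 0.5, depth_shape = 6.25,
                       depth_rate = 6.25, fixed_cells = FALSE, seed = 1L) {
  stopifnot(n_genes >= 1L, n_causal >= 0L, n_causal <= n_genes,
            d_c >= 1L, d_b >= 0L,
            var_xw >= 0, var_xw < 1, var_wy >= 0, var_xby >= 0,
            depth_shape > 0, depth_rate > 0, cells_per_individual >= 1)
  if (var_wy + var_xby >= 1)
    stop("var_wy + var_xby must be < 1 (negative residual variance)")
  structure(list(n_genes = as.integer(n_genes),
                 n_causal = as.integer(n_causal),
                 n_individuals = as.integer(n_individuals),
                 cells_per_individual = cells_per_individual,
                 d_c = as.integer(d_c), d_b = as.integer(d_b),
                 var_xw = var_xw, var_wy = var_wy, var_xby = var_xby,
                 depth_shape = depth_shape, depth_rate = depth_rate,
                 fixed_cells = isTRUE(fixed_cells),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate individuals: covariates and confounded disease labels
#'
#' Draws standard-normal confounders \eqn{X} (n x d_c) and batch
#' covariates \eqn{B} (n x d_b), a confounding direction \eqn{\alpha} and
#' error \eqn{\epsilon_W} from isotropic Gaussians, rescales the error so
#' the realised (sample) variance ratio
#' \eqn{V[X\alpha] / V[X\alpha + \epsilon_W]} equals `var_xw` exactly, and
#' assigns \eqn{W_i \sim \mathrm{Bernoulli}(\mathrm{sigmoid}(\sum_k
#' X_{ik}\alpha_k + \epsilon_{W,i}))}. With `var_xw = 0` the confounding
#' direction is scaled to zero and labels are symmetric coin flips.
#'
#' @param config a [sim_config].
#' @return list with `X`, `B`, `W` (0/1 integer), `alpha`, `eps_w`.
#' @export
simulate_individuals <- function(config) {
  n <- config$n_individuals
  if (n < 2L) stop("need at least 2 individuals")
  X <- matrix(rnorm(n * config$d_c), n, config$d_c)
  B <- if (config$d_b > 0L) matrix(rnorm(n * config$d_b), n, config$d_b)
       else matrix(numeric(0), n, 0L)
  alpha <- rnorm(config$d_c)
  eps <- rnorm(n)
  s <- config$var_xw
  if (s == 0) {
    alpha <- alpha * 0
    lin <- eps
  } else {
    a <- as.numeric(X %*% alpha)
    va <- var(a); ve <- var(eps); cv <- cov(a, eps)
    ## scale eps by the positive root of
    ## c^2 ve + 2 c cov + va (1 - 1/s) = 0, making the realised ratio exact
    disc <- cv^2 - ve * va * (1 - 1 / s)
    cc <- (-cv + sqrt(disc)) / ve
    eps <- cc * eps
    lin <- a + eps
  }
  W <- rbinom(n, 1L, plogis(lin))
  list(X = X, B = B, W = as.integer(W), alpha = alpha, eps_w = eps)
}

#' Simulate gene mean expression under the structural model
#'
#' Gene log-means follow the generalised linear model
#' \deqn{\ln\lambda_{gi} = \tau_g W_i + \sum_k X_{ik}\beta_{kg}
#'   + \sum_l B_{il}\gamma_{lg} + \epsilon_\lambda,}
#' with \eqn{\beta_{kg}, \gamma_{lg} \sim N(0, \sigma^2_{X,B\to Y}/(d_C+d_B))},
#' \eqn{\tau_g \sim N(0, \sigma^2_{W\to Y})} on the randomly chosen causal
#' genes (exactly zero elsewhere), and residual
#' \eqn{\epsilon_\lambda \sim N(0, 1 - \sigma^2_{X,B\to Y} - \sigma^2_{W\to Y})}.
#'
#' @param X,B,W outputs of [simulate_individuals()].
#' @param config a [sim_config].
#' @return list with `lambda` (genes x individuals, positive), `tau`,
#'   `beta` (d_c x genes), `gamma` (d_b x genes), `causal_flags` (logical).
#' @export
simulate_lambda <- function(X, B, W, config) {
  g <- config$n_genes
  n <- nrow(X)
  stopifnot(length(W) == n, ncol(X) == config$d_c, ncol(B) == config$d_b)
  d_tot <- config$d_c + config$d_b
  causal <- rep(FALSE, g)
  causal[sample.int(g, config$n_causal)] <- TRUE
  tau <- numeric(g)
  tau[causal] <- rnorm(config$n_causal, 0, sqrt(config$var_wy))
  beta <- matrix(rnorm(config$d_c * g, 0, sqrt(config$var_xby / d_tot)),
                 config$d_c, g)
  gamma <- matrix(rnorm(config$d_b * g, 0, sqrt(config$var_xby / d_tot)),
                  config$d_b, g)
  resid_sd <- sqrt(1 - config$var_xby - config$var_wy)
  lnl <- t(X %*% beta) + outer(tau, W)             # genes x individuals
  if (config$d_b > 0L) lnl <- lnl + t(B %*% gamma)
  lnl <- lnl + matrix(rnorm(g * n, 0, resid_sd), g, n)
  rownames(lnl) <- sprintf("gene%05d", seq_len(g))
  colnames(lnl) <- sprintf("ind%03d", seq_len(n))
  list(lambda = exp(lnl), tau = tau, beta = beta, gamma = gamma,
       causal_flags = causal)
}

#' Simulate cell-level counts with Gamma sequencing depths
#'
#' Each individual receives `Poisson(cells_per_individual)` cells (floor 1;
#' or exactly that many when `fixed_cells`), each cell a depth
#' \eqn{\rho_j \sim \mathrm{Gamma}(6.25, 6.25)} (mean 1, variance 0.16 by
#' default), and counts \eqn{Y_{gj} \sim \mathrm{Poisson}(\lambda_{gi}\rho_j)}.
#'
#' @param lambda genes x individuals positive matrix.
#' @param config a [sim_config].
#' @return list with `counts` ([cell_counts]), `rho` (per cell),
#'   `individual_of` (per cell).
#' @export
simulate_cells <- function(lambda, config) {
  g <- nrow(lambda); n <- ncol(lambda)
  ncell <- if (config$fixed_cells) rep(as.integer(config$cells_per_individual), n)
           else pmax(1L, rpois(n, config$cells_per_individual))
  ind_of <- rep(colnames(lambda), ncell)
  jn <- length(ind_of)
  rho <- rgamma(jn, shape = config$depth_shape, rate = config$depth_rate)
  rates <- lambda[, rep(seq_len(n), ncell), drop = FALSE] *
    matrix(rho, g, jn, byrow = TRUE)
  y <- matrix(rpois(g * jn, rates), g, jn)
  cell_ids <- sprintf("cell%06d", seq_len(jn))
  counts <- cell_counts(y, gene_ids = rownames(lambda), cell_ids = cell_ids)
  list(counts = counts, rho = stats::setNames(rho, cell_ids),
       individual_of = stats::setNames(ind_of, cell_ids))
}

#' Simulate a complete confounded case-control dataset
#'
#' Runs the full generative model under `config$seed`: individuals and
#' labels, gene means, then cells, returning the inputs the analysis
#' pipeline consumes plus the complete ground truth.
#'
#' @param config a [sim_config].
#' @return list with `counts` ([cell_counts]), `meta` ([cell_meta]) and
#'   `truth` (X, B, W, alpha, tau, beta, gamma, lambda, rho,
#'   causal_flags).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 100, n_individuals = 6,
#'                                    cells_per_individual = 8, seed = 7))
#' table(sim$meta$labels)
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ind <- simulate_individuals(config)
  lam <- simulate_lambda(ind$X, ind$B, ind$W, config)
  cells <- simulate_cells(lam$lambda, config)
  ind_ids <- colnames(lam$lambda)
  meta <- cell_meta(cell_id = names(cells$individual_of),
                    individual_id = unname(cells$individual_of),
                    labels = stats::setNames(ind$W, ind_ids))
  truth <- list(X = ind$X, B = ind$B, W = stats::setNames(ind$W, ind_ids),
                alpha = ind$alpha, tau = lam$tau, beta = lam$beta,
                gamma = lam$gamma, lambda = lam$lambda, rho = cells$rho,
                causal_flags = lam$causal_flags)
  list(counts = cells$counts, meta = meta, truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits the Matrix Market count trio, metadata TSVs and a two-part truth
#' table (per gene: causal flag and effect; per individual: label and
#' covariates).
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_sim_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_matrix(sim$counts, dir)
  write_cell_meta(sim$meta, dir)
  genes <- data.frame(gene = sim$counts$gene_ids,
                      causal = as.integer(sim$truth$causal_flags),
                      tau = sim$truth$tau)
  write.table(genes, file.path(dir, "truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ind <- data.frame(individual_id = names(sim$truth$W),
                    label = unname(sim$truth$W))
  X <- sim$truth$X
  colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (ncol(sim$truth$B)) {
    B <- sim$truth$B
    colnames(B) <- paste0("B", seq_len(ncol(B)))
    ind <- cbind(ind, X, B)
  } else ind <- cbind(ind, X)
  write.table(ind, file.path(dir, "truth_individuals.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
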