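#' Estimate the shared, label-invariant confounder
#'
#' Given observed counts \eqn{Y^{(w)}} and imputed counterfactual counts
#' \eqn{\hat Y^{(1-w)}}, fits the Poisson model
#' \eqn{Y^{(w)}_{gj} \sim \mathrm{Poisson}(\mu_{gi}\,\rho^{(w)}_j)} jointly
#' over both conditions, where \eqn{\mu_{gi}} is shared across conditions
#' (hence label-invariant: it captures whatever the observed and
#' counterfactual profiles agree on, i.e. potential confounding) and the
#' depths \eqn{\rho^{(w)}_j} are condition-specific per cell. Variational
#' Bayes under Gamma(1, 1) priors alternates
#' \deqn{E[\mu_{gi}] = \frac{1 + \sum_{w'} \sum_{j \in S_i} Y^{(w')}_{gj}}
#'                          {1 + \sum_{w'} \sum_{j \in S_i} E[\rho^{(w')}_j]},
#'   \qquad
#'   E[\rho^{(w)}_j] = \frac{1 + \sum_g Y^{(w)}_{gj}}
#'                          {1 + \sum_g E[\mu_{gi(j)}]}}
#' until the maximum relative change of both blocks falls below `tol`.
#' Non-integer counterfactual values are admissible: they enter only
#' through sufficient-statistic sums, which leave the variational means
#' well defined.
#'
#' @param counts observed counts ([cell_counts] or matrix).
#' @param counterfactual an [impute_counterfactual()] result aligned with
#'   `counts`.
#' @param meta a [cell_meta] object.
#' @param max_iter,tol iteration cap and relative-change tolerance.
#'
#' @return An object of class `confounder_fit`: list with `mu` (genes x
#'   individuals, strictly positive), `rho_obs` and `rho_cf` (per-cell
#'   depths of the observed and counterfactual side), `converged`,
#'   `iterations`.
#' @export
estimate_confounder <- function(counts, counterfactual, meta,
                                max_iter = 2000L, tol = 1e-8) {
  stopifnot(inherits(counterfactual, "counterfactual_counts"))
  y <- .counts_matrix(counts)
  yhat <- counterfactual$yhat
  if (!identical(dim(y), dim(yhat)))
    stop("counterfactual matrix is not aligned with the observed counts")
  ind <- .cell_individuals(meta, colnames(y))
  z <- Matrix::sparseMatrix(i = seq_along(ind), j = as.integer(ind), x = 1,
                            dims = c(length(ind), nlevels(ind)))
  num <- 1 + as.matrix(y %*% z) + yhat %*% as.matrix(z)   # 1 + sums over w'
  dimnames(num) <- list(rownames(y), levels(ind))
  ycol_obs <- Matrix::colSums(y)
  ycol_cf <- colSums(yhat)
  ji <- as.integer(ind)
  nind <- nlevels(ind)
  rho_obs <- rep(1, ncol(y))
  rho_cf <- rep(1, ncol(y))
  mu <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    rsum <- as.numeric(rowsum(rho_obs + rho_cf, ji,
                              reorder = TRUE))              # per individual
    mu_new <- sweep(num, 2L, 1 + rsum, "/")
    mu_col <- colSums(mu_new)
    rho_obs_new <- (1 + ycol_obs) / (1 + mu_col[ji])
    rho_cf_new <- (1 + ycol_cf) / (1 + mu_col[ji])
    if (!is.null(mu)) {
      d <- max(max(abs(mu_new - mu) / pmax(abs(mu), 1e-12)),
               max(abs(rho_obs_new - rho_obs) / pmax(rho_obs, 1e-12)),
               max(abs(rho_cf_new - rho_cf) / pmax(rho_cf, 1e-12)))
      if (d < tol) {
        mu <- mu_new; rho_obs <- rho_obs_new; rho_cf <- rho_cf_new
        converged <- TRUE
        break
      }
    }
    mu <- mu_new; rho_obs <- rho_obs_new; rho_cf <- rho_cf_new
  }
  structure(list(mu = mu,
                 rho_obs = stats::setNames(rho_obs, colnames(y)),
                 rho_cf = stats::setNames(rho_cf, colnames(y)),
                 converged = converged, iterations = it),
            class = "confounder_fit")
}

#' Estimate the residual disease effect given the confounder
#'
#' With the confounder fixed at its posterior mean \eqn{\hat\mu_{gi}}, fits
#' \eqn{Y_{gj} \sim \mathrm{Poisson}(\hat\mu_{gi}\,\delta_{gi}\,\rho_j)} on
#' the observed cells only, so \eqn{\delta_{gi}} absorbs whatever the
#' label-invariant confounder cannot explain — the residual disease effect.
#' Variational updates alternate
#' \deqn{E[\delta_{gi}] = \frac{1 + \sum_{j \in S_i} Y_{gj}}
#'                             {1 + \hat\mu_{gi}\sum_{j \in S_i} E[\rho_j]},
#'   \qquad
#'   E[\rho_j] = \frac{1 + \sum_g Y_{gj}}
#'                    {1 + \sum_g \hat\mu_{gi(j)} E[\delta_{gi(j)}]}.}
#' At convergence the Gamma posterior of \eqn{\delta_{gi}} gives
#' \deqn{E[\ln\delta_{gi}] = \psi(1 + \textstyle\sum_j Y_{gj})
#'       - \log(1 + \hat\mu_{gi}\sum_j E[\rho_j]), \qquad
#'       V[\ln\delta_{gi}] = (\textstyle\sum_j Y_{gj})^{-1},}
#' with \eqn{\psi} the digamma function. The log-scale summaries require at
#' least one read for the (gene, individual) pair; pairs with zero total
#' are reported as `NA` there while `E[delta]` stays defined through the
#' pseudo-counts.
#'
#' @param counts observed counts ([cell_counts] or matrix).
#' @param mu genes x individuals matrix of fixed confounder means
#'   (strictly positive), e.g. `estimate_confounder(...)$mu`.
#' @param meta a [cell_meta] object.
#' @param max_iter,tol iteration cap and relative-change tolerance.
#'
#' @return An object of class `residual_fit`: list with `delta`,
#'   `ln_delta_mean`, `ln_delta_var` (genes x individuals; log-scale
#'   entries `NA` where no reads), `rho` (per-cell), `converged`,
#'   `iterations`.
#' @export
estimate_residual <- function(counts, mu, meta, max_iter = 2000L,
                              tol = 1e-8) {
  y <- .counts_matrix(counts)
  mu <- as.matrix(mu)
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("mu must be strictly positive and finite")
  ind <- .cell_individuals(meta, colnames(y))
  if (!identical(dim(mu), c(nrow(y), nlevels(ind))))
    stop("mu must be genes x individuals")
  z <- Matrix::sparseMatrix(i = seq_along(ind), j = as.integer(ind), x = 1,
                            dims = c(length(ind), nlevels(ind)))
  ysum <- as.matrix(y %*% z)
  dimnames(ysum) <- list(rownames(y), levels(ind))
  ycol <- Matrix::colSums(y)
  ji <- as.integer(ind)
  rho <- rep(1, ncol(y))
  delta <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    rsum <- as.numeric(rowsum(rho, ji))
    delta_new <- (1 + ysum) / (1 + sweep(mu, 2L, rsum, "*"))
    md_col <- colSums(mu * delta_new)
    rho_new <- (1 + ycol) / (1 + md_col[ji])
    if (!is.null(delta)) {
      d <- max(max(abs(delta_new - delta) / pmax(abs(delta), 1e-12)),
               max(abs(rho_new - rho) / pmax(rho, 1e-12)))
      if (d < tol) {
        delta <- delta_new; rho <- rho_new; converged <- TRUE
        break
      }
    }
    delta <- delta_new
    rho <- rho_new
  }
  rsum <- as.numeric(rowsum(rho, ji))
  ln_mean <- digamma(1 + ysum) - log1p(sweep(mu, 2L, rsum, "*"))
  ln_var <- 1 / ysum
  zero <- ysum == 0
  ln_mean[zero] <- NA_real_
  ln_var[zero] <- NA_real_
  structure(list(delta = delta, ln_delta_mean = ln_mean,
                 ln_delta_var = ln_var,
                 rho = stats::setNames(rho, colnames(y)),
                 converged = converged, iterations = it),
            class = "residual_fit")
}

#' @export
print.confounder_fit <- function(x, ...) {
  cat(sprintf("confounder_fit: %d genes x %d individuals (%d iterations, %s)\n",
              nrow(x$mu), ncol(x$mu), x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
print.residual_fit <- function(x, ...) {
  cat(sprintf("residual_fit: %d genes x %d individuals (%d iterations, %s)\n",
              nrow(x$delta), ncol(x$delta), x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
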