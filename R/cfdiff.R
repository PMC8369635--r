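#' Per-gene differential expression table from a pseudo-bulk matrix
#'
#' Ranks genes by the two-sided Wilcoxon rank-sum test comparing the
#' per-individual values of each gene between case and control
#' individuals, and attaches multiplicity-adjusted q-values.
#'
#' @param x genes x individuals numeric matrix (column names = individual
#'   ids) — any pseudo-bulk estimate, a confounder matrix, or the residual
#'   disease effect.
#' @param meta a [cell_meta]; only its labels are used.
#' @param p_adjust method for [adjust_multiplicity()] (default `"bh"`).
#' @return data.frame with columns `gene`, `n_case`, `n_ctrl`,
#'   `wilcoxon_p`, `q_value`.
#' @export
deg_table <- function(x, meta, p_adjust = "bh") {
  lab <- meta$labels[colnames(x)]
  if (anyNA(lab)) stop("individuals missing from metadata labels")
  is_case <- lab == 1L
  if (!any(is_case) || all(is_case))
    stop("need individuals of both labels")
  p <- .ranksum_p_rows(x, is_case)
  data.frame(gene = rownames(x),
             n_case = sum(is_case), n_ctrl = sum(!is_case),
             wilcoxon_p = unname(p),
             q_value = unname(adjust_multiplicity(p, p_adjust)),
             stringsAsFactors = FALSE)
}

## run the matching / imputation / decomposition chain on one stratum
.fit_stratum <- function(counts, meta, rank, knn, impute, transform,
                         ridge, max_iter, tol, z_scale, p_adjust) {
  emb <- embed_cells(counts, rank = rank, transform = transform)
  matches <- match_opposite(emb, meta, k = knn)
  cf <- impute_counterfactual(counts, matches, method = impute,
                              ridge = ridge, max_iter = max_iter)
  conf <- estimate_confounder(counts, cf, meta, max_iter = max_iter,
                              tol = tol)
  res <- estimate_residual(counts, conf$mu, meta, max_iter = max_iter,
                           tol = tol)
  tab <- deg_table(res$delta, meta, p_adjust = p_adjust)
  eff <- t(vapply(seq_len(nrow(res$delta)), function(g) {
    a <- ade_se(res$ln_delta_mean[g, ], res$ln_delta_var[g, ],
                z_scale = z_scale)
    c(a$ade, a$se, a$z)
  }, numeric(3)))
  tab$ADE <- eff[, 1L]
  tab$SE <- eff[, 2L]
  tab$Z <- eff[, 3L]
  list(table = tab, mu = conf$mu, delta = res$delta,
       ln_delta_mean = res$ln_delta_mean, ln_delta_var = res$ln_delta_var,
       rho_obs = conf$rho_obs, rho_cf = conf$rho_cf, rho = res$rho,
       singular_values = emb$singular_values)
}

#' Counterfactual confounder-adjusted differential expression
#'
#' Fits the full individual-level causal differential expression model to
#' a case-control single-cell count matrix. Within each cell-type stratum
#' (or globally when no annotation is present) the procedure: (1) embeds
#' all cells jointly by truncated SVD and matches every cell to its `knn`
#' nearest neighbours among opposite-condition cells; (2) imputes each
#' cell's counterfactual expression from its matches by penalised Poisson
#' regression ([impute_counterfactual()]); (3) estimates the shared,
#' label-invariant confounder \eqn{\mu_{gi}} from observed plus
#' counterfactual profiles ([estimate_confounder()]); (4) holding
#' \eqn{\hat\mu} fixed, estimates the residual disease effect
#' \eqn{\delta_{gi}} with posterior summaries of \eqn{\ln\delta}
#' ([estimate_residual()]); and (5) tests each gene by Wilcoxon rank-sum on
#' the adjusted values and summarises the effect by the inverse-variance
#' average disease effect (ADE), its standard error and Wald Z.
#'
#' A stratum whose individuals carry only one disease label violates the
#' overlap assumption and is skipped with a warning.
#'
#' @param counts a [cell_counts] object.
#' @param meta a [cell_meta]; if it contains a `cell_type` column the
#'   pipeline runs independently inside each cell type.
#' @param rank spectral embedding rank (default 50).
#' @param knn neighbours per cell in cross-condition matching
#'   (default 100).
#' @param impute `"poisson_reg"` (default) or `"knn_average"`.
#' @param transform pre-decomposition transform, see [embed_cells()].
#' @param ridge L2 penalty of the imputation regression.
#' @param max_iter,tol iteration caps and tolerances of the variational
#'   and regression solvers.
#' @param z_scale per-individual Wald standardisation, see [ade_se()].
#' @param p_adjust q-value method, see [adjust_multiplicity()].
#'
#' @return An object of class `cfdiff`: list with `table` (combined
#'   per-stratum DEG table: gene, celltype, n_case, n_ctrl, wilcoxon_p,
#'   q_value, ADE, SE, Z), `strata` (per-stratum fits holding `mu`,
#'   `delta`, `ln_delta_mean`, `ln_delta_var`, depths and singular
#'   values), `skipped` (names of strata without label overlap), and the
#'   `call`. Methods: `print`, `summary`, `coef`.
#' @seealso [pseudobulk()] for unadjusted aggregates, [simulate_dataset()]
#'   for the benchmark generator.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 60, n_individuals = 8,
#'                                    cells_per_individual = 15, seed = 3))
#' fit <- cfdiff(sim$counts, sim$meta, rank = 5, knn = 5)
#' head(fit$table)
cfdiff <- function(counts, meta, rank = 50L, knn = 100L,
                   impute = c("poisson_reg", "knn_average"),
                   transform = "log1p-unit", ridge = 1e-4,
                   max_iter = 2000L, tol = 1e-8,
                   z_scale = c("sd", "var"), p_adjust = "bh") {
  impute <- match.arg(impute)
  z_scale <- match.arg(z_scale)
  stopifnot(inherits(counts, "cell_counts"), inherits(meta, "cell_meta"))
  has_types <- !is.null(meta$cells$cell_type)
  strata_cells <- if (has_types)
    split(meta$cells$cell_id, meta$cells$cell_type)
  else list(all = meta$cells$cell_id)
  strata <- list()
  tables <- list()
  skipped <- character(0)
  for (ct in names(strata_cells)) {
    ids <- intersect(counts$cell_ids, strata_cells[[ct]])
    sub_meta <- .subset_meta(meta, ids)
    labs <- sub_meta$labels[unique(sub_meta$cells$individual_id)]
    if (length(unique(labs)) < 2L) {
      warning("stratum '", ct, "' has individuals of only one label; skipped")
      skipped <- c(skipped, ct)
      next
    }
    sub_counts <- cell_counts(counts$counts[, ids, drop = FALSE])
    fit <- .fit_stratum(sub_counts, sub_meta, rank = rank, knn = knn,
                        impute = impute, transform = transform,
                        ridge = ridge, max_iter = max_iter, tol = tol,
                        z_scale = z_scale, p_adjust = p_adjust)
    fit$table <- cbind(fit$table[, "gene", drop = FALSE],
                       celltype = ct,
                       fit$table[, setdiff(names(fit$table), "gene")])
    strata[[ct]] <- fit
    tables[[ct]] <- fit$table
  }
  if (!length(strata))
    stop("no stratum satisfies the overlap assumption")
  structure(list(table = do.call(rbind, c(tables, make.row.names = FALSE)),
                 strata = strata, skipped = skipped,
                 call = match.call()),
            class = "cfdiff")
}

#' @export
print.cfdiff <- function(x, ...) {
  ng <- length(unique(x$table$gene))
  cat(sprintf("cfdiff fit: %d genes, %d stratum/strata (%s)\n", ng,
              length(x$strata), paste(names(x$strata), collapse = ", ")))
  if (length(x$skipped))
    cat("skipped (no label overlap):", paste(x$skipped, collapse = ", "),
        "\n")
  cat(sprintf("genes at q < 0.01: %d; q < 0.05: %d\n",
              sum(x$table$q_value < 0.01, na.rm = TRUE),
              sum(x$table$q_value < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.cfdiff <- function(object, n = 10L, ...) {
  tab <- object$table[order(object$table$wilcoxon_p), ]
  cat("Top genes by Wilcoxon rank-sum p-value:\n")
  print(utils::head(tab, n), row.names = FALSE, digits = 3)
  invisible(tab)
}

#' Extract average disease effects
#'
#' @param object a [cfdiff] fit.
#' @param ... unused.
#' @return named numeric vector of ADE values (log-scale effect sizes),
#'   names `gene` or `celltype:gene` when stratified.
#' @export
coef.cfdiff <- function(object, ...) {
  tab <- object$table
  nm <- if (length(object$strata) > 1L)
    paste(tab$celltype, tab$gene, sep = ":") else tab$gene
  stats::setNames(tab$ADE, nm)
}
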