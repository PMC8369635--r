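#' Marker-gene table
#'
#' Binary genes x cell-types membership matrix designating which marker
#' genes are active in which cell type.
#'
#' @param L binary matrix (genes x types) or data.frame coercible to it.
#' @param gene_ids,type_names identifiers; default from dimnames.
#' @return object of class `marker_table`: list with `L` (0/1 matrix),
#'   `gene_ids`, `type_names`.
#' @export
marker_table <- function(L, gene_ids = rownames(L),
                         type_names = colnames(L)) {
  L <- as.matrix(L)
  if (!all(L %in% c(0, 1))) stop("marker table entries must be 0/1")
  if (is.null(gene_ids) || is.null(type_names))
    stop("marker table needs gene and cell-type names")
  if (any(colSums(L) == 0))
    stop("every cell type needs at least one marker gene")
  storage.mode(L) <- "double"
  dimnames(L) <- list(gene_ids, type_names)
  structure(list(L = L, gene_ids = as.character(gene_ids),
                 type_names = as.character(type_names)),
            class = "marker_table")
}

#' Read a long-format marker TSV (columns: gene, cell_type)
#' @param path TSV path with header columns `gene` and `cell_type`.
#' @return a [marker_table].
#' @export
read_marker_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "cell_type") %in% names(d)))
    stop("marker TSV needs columns gene, cell_type")
  genes <- sort(unique(d$gene))
  types <- sort(unique(d$cell_type))
  L <- matrix(0, length(genes), length(types),
              dimnames = list(genes, types))
  L[cbind(match(d$gene, genes), match(d$cell_type, types))] <- 1
  marker_table(L)
}

#' Unit-norm marker-gene feature vectors per cell
#'
#' Restricts the count matrix to the marker genes present, transforms
#' counts by `log1p` and scales each cell's vector to unit L2 norm, giving
#' the directional features the von Mises-Fisher mixture classifies. Cells
#' with no marker reads cannot be placed on the sphere and are flagged
#' unassignable.
#'
#' @param counts a [cell_counts] or genes x cells matrix.
#' @param markers a [marker_table].
#' @return list with `m` (d x cells matrix of unit vectors; zero columns
#'   for unassignable cells), `assignable` (logical per cell), `gene_ids`
#'   (the d marker genes used), `L` (marker matrix restricted to them).
#' @export
normalize_marker_features <- function(counts, markers) {
  stopifnot(inherits(markers, "marker_table"))
  y <- .counts_matrix(counts)
  common <- intersect(rownames(y), markers$gene_ids)
  if (!length(common)) stop("no marker genes present in the count matrix")
  m <- as.matrix(y[common, , drop = FALSE])
  m <- log1p(m)
  nrm <- sqrt(colSums(m^2))
  assignable <- nrm > 0
  nrm[!assignable] <- 1
  m <- sweep(m, 2L, nrm, "/")
  list(m = m, assignable = assignable, gene_ids = common,
       L = markers$L[common, , drop = FALSE])
}

#' Constrained von Mises-Fisher mixture by stochastic EM
#'
#' Models each cell's unit marker-feature vector \eqn{m_j} as von
#' Mises-Fisher with a cell-type mean direction \eqn{\theta_k} and a
#' concentration \eqn{\kappa} shared across types. The mean directions are
#' constrained to the marker support: \eqn{\theta_k} is zero outside the
#' marker genes of type \eqn{k}. Stochastic EM alternates sampling the
#' type indicator of each cell from the discrete distribution proportional
#' to \eqn{\exp(\kappa\, m_j^\top \theta_k)} with the constrained M-step
#' \deqn{\theta_k \leftarrow \frac{\sum_j z_{jk}\, m_j \circ l_k}
#'       {\lVert \sum_j z_{jk}\, m_j \circ l_k \rVert}, \qquad
#'       \kappa \leftarrow \frac{r d - r^3}{1 - r^2},}
#' where \eqn{r = \lVert \sum_j m_j \rVert / n} is the global resultant
#' length (capped at \eqn{1 - 10^{-8}}) and \eqn{d} the feature dimension.
#' The final hard assignment is the mode over the last `collect` sampled
#' E-steps.
#'
#' @param features a [normalize_marker_features()] result.
#' @param n_steps number of EM steps (default 100).
#' @param burn_in steps discarded before assignments are collected
#'   (default 50).
#' @param collect number of final E-steps whose samples vote on the modal
#'   assignment (default 10).
#' @param seed optional RNG seed.
#' @param kappa_in_estep include the concentration in the sampling
#'   probabilities (default `TRUE`, consistent with the stated
#'   likelihood); `FALSE` samples proportional to
#'   \eqn{\exp(m_j^\top\theta_k)}.
#'
#' @return object of class `vmf_model`: list with `theta` (d x K unit
#'   vectors on the marker support), `kappa`, `r`, `assignment` (per-cell
#'   type name; `NA` for unassignable cells), `scores` (cells x K cosine
#'   scores at the final model).
#' @export
fit_vmf_mixture <- function(features, n_steps = 100L, burn_in = 50L,
                            collect = 10L, seed = NULL,
                            kappa_in_estep = TRUE) {
  stopifnot(n_steps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  m <- features$m[, features$assignable, drop = FALSE]
  L <- features$L
  K <- ncol(L)
  if (K < 2L) stop("need at least two cell types")
  d <- nrow(m); n <- ncol(m)
  ## global resultant length and closed-form concentration
  r <- sqrt(sum(rowSums(m)^2)) / n
  r <- min(r, 1 - 1e-8)
  kappa <- (r * d - r^3) / (1 - r^2)
  init_theta <- sweep(L, 2L, sqrt(colSums(L^2)), "/")  # marker centroids
  theta <- init_theta
  votes <- matrix(0L, n, K)
  keep_from <- max(n_steps - collect + 1L, min(burn_in + 1L, n_steps))
  for (step in seq_len(n_steps)) {
    sc <- crossprod(m, theta)                          # n x K
    logit <- if (kappa_in_estep) kappa * sc else sc
    logit <- logit - apply(logit, 1L, max)
    pr <- exp(logit)
    pr <- pr / rowSums(pr)
    ## inverse-CDF categorical sampling, one uniform per cell
    u <- runif(n)
    cum <- t(apply(pr, 1L, cumsum))
    z <- rowSums(u > cum) + 1L
    z[z > K] <- K
    for (k in seq_len(K)) {
      if (!any(z == k)) {
        warning("empty cluster ", colnames(L)[k],
                "; reinitialised from marker centroid")
        theta[, k] <- init_theta[, k]
        next
      }
      v <- rowSums(m[, z == k, drop = FALSE]) * L[, k]
      nv <- sqrt(sum(v^2))
      if (nv > 0) theta[, k] <- v / nv else theta[, k] <- init_theta[, k]
    }
    if (step >= keep_from)
      votes[cbind(seq_len(n), z)] <- votes[cbind(seq_len(n), z)] + 1L
  }
  modal <- max.col(votes, ties.method = "first")
  assignment <- rep(NA_character_, length(features$assignable))
  assignment[features$assignable] <- colnames(L)[modal]
  names(assignment) <- colnames(features$m)
  scores <- matrix(NA_real_, length(assignment), K,
                   dimnames = list(names(assignment), colnames(L)))
  scores[features$assignable, ] <- crossprod(m, theta)
  structure(list(theta = theta, kappa = kappa, r = r,
                 assignment = assignment, scores = scores),
            class = "vmf_model")
}

#' @export
print.vmf_model <- function(x, ...) {
  cat(sprintf("vmf_model: %d cell types, kappa = %.3g\n",
              ncol(x$theta), x$kappa))
  print(table(x$assignment, useNA = "ifany"))
  invisible(x)
}

#' Annotate cells with marker-constrained vMF mixture
#'
#' Convenience wrapper: [normalize_marker_features()] then
#' [fit_vmf_mixture()].
#'
#' @param counts a [cell_counts].
#' @param markers a [marker_table].
#' @param ... passed to [fit_vmf_mixture()].
#' @return named character vector of cell-type assignments per cell
#'   (`NA` for cells without marker reads), with the fitted `vmf_model`
#'   attached as attribute `"model"`.
#' @export
annotate_cells <- function(counts, markers, ...) {
  ft <- normalize_marker_features(counts, markers)
  fit <- fit_vmf_mixture(ft, ...)
  structure(fit$assignment, model = fit)
}
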