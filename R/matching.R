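#' Spectral embedding of cells
#'
#' Truncated singular value decomposition of the (transformed) genes x cells
#' matrix; cell coordinates are the right singular vectors scaled by the
#' singular values, i.e. the classical principal-component scores used for
#' cell-cell distances.
#'
#' The default transform is `log1p` of the counts followed by scaling each
#' cell column to unit L2 norm, which makes distances robust to sequencing
#' depth. The decomposition is exact: the Gram matrix on the smaller
#' dimension is eigendecomposed, so coordinates agree with a dense SVD up to
#' component sign (signs are fixed deterministically by making the largest
#' loading of each component positive).
#'
#' @param counts a [cell_counts] object or genes x cells matrix.
#' @param rank number of components; clipped to `min(G, J)` with a warning.
#' @param transform `"log1p-unit"` (default), `"log1p"` or `"raw"`.
#'
#' @return An object of class `cell_embedding`: list with `coords` (cells x
#'   rank matrix, rownames = cell ids), `singular_values` (non-increasing),
#'   `rank`, `transform`.
#' @export
embed_cells <- function(counts, rank = 50L,
                        transform = c("log1p-unit", "log1p", "raw")) {
  transform <- match.arg(transform)
  y <- .counts_matrix(counts)
  g <- nrow(y); j <- ncol(y)
  stopifnot(rank >= 1L)
  if (rank > min(g, j)) {
    warning("rank ", rank, " exceeds min(G, J) = ", min(g, j), "; clipped")
    rank <- min(g, j)
  }
  x <- if (transform == "raw") y else {
    if (is(y, "sparseMatrix")) { t <- y; t@x <- log1p(t@x); t }
    else log1p(y)
  }
  if (transform == "log1p-unit") {
    nrm <- sqrt(Matrix::colSums(x^2))
    nrm[nrm == 0] <- 1                       # all-zero cells stay zero
    x <- x %*% Matrix::Diagonal(x = 1 / nrm)
  }
  ## simulated and QC-filtered matrices are dense enough that BLAS-level
  ## dense Gram products beat sparse ones; fall back to sparse only when
  ## the dense copy would be large
  xd <- if (as.numeric(g) * j <= 5e7) as.matrix(x) else x
  if (j <= g) {
    gram <- as.matrix(Matrix::crossprod(xd))  # J x J
    ev <- eigen(gram, symmetric = TRUE)
    d <- sqrt(pmax(ev$values[seq_len(rank)], 0))
    v <- ev$vectors[, seq_len(rank), drop = FALSE]
  } else {
    gram <- as.matrix(Matrix::tcrossprod(xd)) # G x G
    ev <- eigen(gram, symmetric = TRUE)
    d <- sqrt(pmax(ev$values[seq_len(rank)], 0))
    u <- ev$vectors[, seq_len(rank), drop = FALSE]
    v <- as.matrix(Matrix::crossprod(xd, u))
    pos <- d > 1e-12
    v[, pos] <- sweep(v[, pos, drop = FALSE], 2L, d[pos], "/")
    v[, !pos] <- 0
  }
  ## deterministic sign: largest-magnitude entry of each component positive
  for (kk in seq_len(rank)) {
    m <- which.max(abs(v[, kk]))
    if (length(m) && v[m, kk] < 0) v[, kk] <- -v[, kk]
  }
  coords <- sweep(v, 2L, d, "*")
  rownames(coords) <- colnames(y)
  structure(list(coords = coords, singular_values = d, rank = rank,
                 transform = transform),
            class = "cell_embedding")
}

#' @export
print.cell_embedding <- function(x, ...) {
  cat(sprintf("cell_embedding: %d cells, rank %d (%s transform)\n",
              nrow(x$coords), x$rank, x$transform))
  invisible(x)
}

#' Cross-condition k-nearest-neighbour matching
#'
#' For every cell with disease label \eqn{w}, finds the `k` nearest cells
#' (Euclidean distance in the spectral embedding) among cells belonging to
#' individuals with the opposite label \eqn{1 - w}. These matched
#' opposite-condition cells are the basis for counterfactual imputation.
#'
#' The search is exact (chunked brute force); ties in distance are broken
#' by lower cell index, making the result deterministic. When fewer than
#' `k` opposite-condition cells exist, all of them are returned with a
#' warning.
#'
#' @param embedding a [embed_cells()] result.
#' @param meta a [cell_meta] object.
#' @param k requested number of neighbours (>= 1).
#'
#' @return An object of class `match_set`: list with `idx` and `dist`
#'   (k x J matrices, NA-padded when clipped), `k`, `labels` (per cell),
#'   `cell_ids`.
#' @export
match_opposite <- function(embedding, meta, k = 100L) {
  stopifnot(inherits(embedding, "cell_embedding"), k >= 1L)
  coords <- embedding$coords
  cells <- rownames(coords)
  lab <- .cell_labels(meta, cells)
  n0 <- sum(lab == 0L); n1 <- sum(lab == 1L)
  if (n0 == 0L || n1 == 0L)
    stop("no opposite-condition cells: overlap assumption violated")
  j <- length(lab)
  idx <- matrix(NA_integer_, k, j)
  dst <- matrix(NA_real_, k, j)
  clipped <- FALSE
  for (w in c(0L, 1L)) {
    q <- which(lab == w)
    cand <- which(lab != w)
    keff <- min(k, length(cand))
    if (keff < k) clipped <- TRUE
    cm <- coords[cand, , drop = FALSE]
    cn <- rowSums(cm^2)
    chunk <- 512L
    for (s in seq(1L, length(q), by = chunk)) {
      qi <- q[s:min(s + chunk - 1L, length(q))]
      qm <- coords[qi, , drop = FALSE]
      qn <- rowSums(qm^2)
      d2 <- outer(cn, qn, "+") - 2 * tcrossprod(cm, qm)  # cand x query
      for (c2 in seq_along(qi)) {
        o <- order(d2[, c2], cand)[seq_len(keff)]
        idx[seq_len(keff), qi[c2]] <- cand[o]
        dst[seq_len(keff), qi[c2]] <- sqrt(pmax(d2[o, c2], 0))
      }
    }
  }
  if (clipped)
    warning("fewer than k = ", k,
            " opposite-condition cells available; matches clipped")
  colnames(idx) <- colnames(dst) <- cells
  structure(list(idx = idx, dist = dst, k = k, labels = lab,
                 cell_ids = cells),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("match_set: %d cells matched to up to %d opposite-condition neighbours\n",
              ncol(x$idx), x$k))
  invisible(x)
}
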