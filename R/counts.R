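#' Single-cell count matrix
#'
#' Container for a genes x cells matrix of non-negative integer UMI/read
#' counts, stored sparsely, together with gene and cell identifiers. All
#' downstream steps (pseudo-bulk aggregation, spectral matching,
#' counterfactual imputation, confounder decomposition) consume this type.
#'
#' @param counts a genes x cells matrix (dense or any \pkg{Matrix} sparse
#'   class) of non-negative integer counts.
#' @param gene_ids character vector of unique gene identifiers (rows).
#'   Defaults to `rownames(counts)`.
#' @param cell_ids character vector of unique cell barcodes (columns).
#'   Defaults to `colnames(counts)`.
#'
#' @return An object of class `cell_counts`: a list with elements `counts`
#'   (a `dgCMatrix`), `gene_ids` and `cell_ids`.
#' @export
#' @examples
#' y <- matrix(c(3, 0, 0, 1), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' cc <- cell_counts(y)
#' dim(cc)
cell_counts <- function(counts, gene_ids = rownames(counts),
                        cell_ids = colnames(counts)) {
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts))
    stop("length(gene_ids) != nrow(counts): ", length(gene_ids),
         " vs ", nrow(counts))
  if (length(cell_ids) != ncol(counts))
    stop("length(cell_ids) != ncol(counts): ", length(cell_ids),
         " vs ", ncol(counts))
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  m <- if (is.matrix(counts)) {
    storage.mode(counts) <- "double"
    methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  } else {
    methods::as(methods::as(methods::as(counts, "dMatrix"),
                            "generalMatrix"), "CsparseMatrix")
  }
  if (length(m@x)) {
    if (any(m@x < 0)) stop("negative counts are not allowed")
    if (any(m@x != floor(m@x))) stop("counts must be integral")
  }
  dimnames(m) <- list(gene_ids, cell_ids)
  structure(list(counts = m, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "cell_counts")
}

#' @export
dim.cell_counts <- function(x) dim(x$counts)

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("cell_counts: %d genes x %d cells, %d stored values\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

## accept a cell_counts object or a bare (sparse or dense) matrix
.counts_matrix <- function(x) {
  if (inherits(x, "cell_counts")) return(x$counts)
  if (is.matrix(x) || is(x, "Matrix")) return(x)
  stop("expected a cell_counts object or a matrix")
}

.dense_counts <- function(x) {
  m <- .counts_matrix(x)
  if (is.matrix(m)) m else as.matrix(m)
}

#' Read a sparse count matrix in Matrix Market triplet format
#'
#' Reads the 10x-style trio of files: a coordinate Matrix Market file
#' (1-based indices on disk, genes as rows, cells as columns) plus gene and
#' barcode TSVs whose first column holds the identifiers.
#'
#' @param matrix_path path to the `.mtx` coordinate file with integer values.
#' @param genes_path path to the gene id TSV (no header; first column used).
#' @param barcodes_path path to the barcode TSV (no header; first column used).
#'
#' @return A [cell_counts] object. Zero entries are never materialised.
#' @export
read_count_matrix <- function(matrix_path, genes_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- read.delim(genes_path, header = FALSE,
                      stringsAsFactors = FALSE)[[1L]]
  cells <- read.delim(barcodes_path, header = FALSE,
                      stringsAsFactors = FALSE)[[1L]]
  if (nrow(m) != length(genes))
    stop("matrix declares ", nrow(m), " rows but ", length(genes),
         " gene ids were read")
  if (ncol(m) != length(cells))
    stop("matrix declares ", ncol(m), " columns but ", length(cells),
         " barcodes were read")
  cell_counts(m, gene_ids = genes, cell_ids = cells)
}

#' Write a count matrix as Matrix Market + id files
#'
#' Inverse of [read_count_matrix()]; the round trip is lossless.
#'
#' @param x a [cell_counts] object.
#' @param dir output directory (created if missing). Files `matrix.mtx`,
#'   `genes.tsv` and `barcodes.tsv` are written inside.
#' @return invisibly, the three file paths.
#' @export
write_count_matrix <- function(x, dir) {
  stopifnot(inherits(x, "cell_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Matrix::writeMM(x$counts, paths[1L])
  writeLines(x$gene_ids, paths[2L])
  writeLines(x$cell_ids, paths[3L])
  invisible(paths)
}
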