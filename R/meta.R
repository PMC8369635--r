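#' Per-cell metadata: individuals, disease labels, optional cell types
#'
#' Maps every cell to exactly one individual and every individual to a
#' binary disease label (1 = case, 0 = control). An optional per-cell
#' cell-type annotation drives stratified analysis.
#'
#' @param cell_id character vector of cell barcodes.
#' @param individual_id character vector, same length, the individual each
#'   cell belongs to.
#' @param labels named vector (names = individual ids) with values in
#'   `{0, 1}`; anything else is an error, no coercion is attempted.
#' @param celltype optional character vector, same length as `cell_id`.
#'
#' @return An object of class `cell_meta` with elements `cells` (data.frame
#'   `cell_id`, `individual_id`[, `cell_type`]) and `labels` (named integer).
#' @export
cell_meta <- function(cell_id, individual_id, labels, celltype = NULL) {
  cell_id <- as.character(cell_id)
  individual_id <- as.character(individual_id)
  if (length(cell_id) != length(individual_id))
    stop("cell_id and individual_id lengths differ")
  if (anyDuplicated(cell_id)) stop("duplicate cell ids in metadata")
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop("labels must be uniquely named by individual id")
  lv <- labels
  if (is.factor(lv)) lv <- as.character(lv)
  if (is.character(lv)) {
    ok <- lv %in% c("0", "1")
    if (!all(ok)) stop("labels must be 0 or 1; got: ",
                       paste(unique(lv[!ok]), collapse = ", "))
    lv <- as.integer(lv)
  }
  if (!is.numeric(lv) || any(is.na(lv)) || !all(lv %in% c(0, 1)))
    stop("labels must be 0 or 1")
  lv <- stats::setNames(as.integer(lv), names(labels))
  missing_ind <- setdiff(unique(individual_id), names(lv))
  if (length(missing_ind))
    stop("no disease label for individual(s): ",
         paste(utils::head(missing_ind, 5L), collapse = ", "))
  if (length(unique(lv[unique(individual_id)])) < 2L)
    stop("both disease labels must be present among individuals ",
         "(overlap assumption)")
  cells <- data.frame(cell_id = cell_id, individual_id = individual_id,
                      stringsAsFactors = FALSE)
  if (!is.null(celltype)) {
    if (length(celltype) != length(cell_id))
      stop("celltype length differs from cell_id")
    cells$cell_type <- as.character(celltype)
  }
  structure(list(cells = cells, labels = lv), class = "cell_meta")
}

#' @export
print.cell_meta <- function(x, ...) {
  cat(sprintf("cell_meta: %d cells, %d individuals (%d case / %d control)%s\n",
              nrow(x$cells), length(x$labels), sum(x$labels == 1L),
              sum(x$labels == 0L),
              if (!is.null(x$cells$cell_type))
                sprintf(", %d cell types",
                        length(unique(x$cells$cell_type))) else ""))
  invisible(x)
}

## per-cell label vector aligned with cell order of `cell_ids`
.cell_labels <- function(meta, cell_ids) {
  idx <- match(cell_ids, meta$cells$cell_id)
  if (anyNA(idx)) stop("cells missing from metadata: ",
                       paste(utils::head(cell_ids[is.na(idx)], 5L),
                             collapse = ", "))
  unname(meta$labels[meta$cells$individual_id[idx]])
}

## per-cell individual factor aligned with `cell_ids`
.cell_individuals <- function(meta, cell_ids) {
  idx <- match(cell_ids, meta$cells$cell_id)
  if (anyNA(idx)) stop("cells missing from metadata")
  factor(meta$cells$individual_id[idx])
}

## restrict metadata to a subset of cells, without re-running the
## both-labels constructor check (strata may legitimately violate it and
## are then skipped by the pipeline)
.subset_meta <- function(meta, cell_ids) {
  keep <- meta$cells$cell_id %in% cell_ids
  cells <- meta$cells[keep, , drop = FALSE]
  labels <- meta$labels[intersect(names(meta$labels),
                                  unique(cells$individual_id))]
  structure(list(cells = cells, labels = labels), class = "cell_meta")
}

#' Read cell and individual metadata TSVs
#'
#' Two headered tab-separated files: per-cell
#' `(cell_id, individual_id[, cell_type])` and per-individual
#' `(individual_id, label)` with labels in `{0, 1}`.
#'
#' @param cells_path path to the per-cell TSV.
#' @param labels_path path to the per-individual label TSV.
#' @return A [cell_meta] object.
#' @export
read_cell_meta <- function(cells_path, labels_path) {
  cells <- read.delim(cells_path, stringsAsFactors = FALSE)
  lab <- read.delim(labels_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!all(c("cell_id", "individual_id") %in% names(cells)))
    stop("per-cell metadata needs columns cell_id, individual_id")
  if (!all(c("individual_id", "label") %in% names(lab)))
    stop("label table needs columns individual_id, label")
  cell_meta(cells$cell_id, cells$individual_id,
            labels = stats::setNames(lab$label, lab$individual_id),
            celltype = cells$cell_type)
}

#' Write cell and individual metadata TSVs
#'
#' @param meta a [cell_meta] object.
#' @param dir output directory; writes `cells.tsv` and `labels.tsv`.
#' @return invisibly, the two file paths.
#' @export
write_cell_meta <- function(meta, dir) {
  stopifnot(inherits(meta, "cell_meta"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("cells.tsv", "labels.tsv"))
  write.table(meta$cells, paths[1L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(individual_id = names(meta$labels),
                         label = unname(meta$labels)),
              paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
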