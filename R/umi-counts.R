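#' Construct a gene-by-cell UMI count container
#'
#' Light container pairing a sparse gene-by-cell UMI count matrix with its
#' gene and cell metadata. Genes carry a mitochondrial flag (by convention,
#' mouse mito genes are named with the `mt-` prefix); cells carry sample and
#' condition labels and, for synthetic data, the planted class.
#'
#' @param counts Gene-by-cell matrix of nonnegative integer counts (coerced to
#'   `Matrix::dgCMatrix`). Row names are gene ids, column names cell barcodes.
#' @param genes Optional tibble with columns `gene` and logical `mito`;
#'   defaults to row names with `mito = grepl("^mt-", gene)`.
#' @param cells Optional tibble with a `cell` column (plus `sample`,
#'   `condition`, ...); defaults to the column names.
#' @return A `umi_counts` object.
#' @export
umi_counts <- function(counts, genes = NULL, cells = NULL) {
  dn <- dimnames(counts)
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(counts, "dMatrix"), "CsparseMatrix")
  if (is.null(dimnames(counts)) && !is.null(dn)) dimnames(counts) <- dn
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      (is.null(colnames(counts)) && ncol(counts) > 0)) {
    data_error("`counts` must have gene row names and cell column names.")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    data_error("gene and cell ids must be unique.")
  }
  if (any(counts@x < 0) || any(counts@x != floor(counts@x))) {
    data_error("counts must be nonnegative integers.")
  }
  genes <- if (is.null(genes)) {
    tibble(gene = rownames(counts), mito = grepl("^mt-", rownames(counts)))
  } else {
    as_tibble(genes)
  }
  if (!all(c("gene") %in% names(genes)) ||
      !identical(genes$gene, rownames(counts) %||% character(0))) {
    data_error("`genes$gene` must match the count matrix row names in order.")
  }
  if (!"mito" %in% names(genes)) genes$mito <- grepl("^mt-", genes$gene)
  cells <- if (is.null(cells)) tibble(cell = colnames(counts)) else as_tibble(cells)
  if (!"cell" %in% names(cells) ||
      !identical(cells$cell, colnames(counts) %||% character(0))) {
    data_error("`cells$cell` must match the count matrix column names in order.")
  }
  structure(list(counts = counts, genes = genes, cells = cells),
            class = "umi_counts")
}

#' @export
print.umi_counts <- function(x, ...) {
  cat(sprintf("<umi_counts> %d genes x %d cells (%d mito genes)\n",
              nrow(x$counts), ncol(x$counts), sum(x$genes$mito)))
  if ("condition" %in% names(x$cells)) {
    print(dplyr::count(x$cells, .data$condition), ...)
  }
  invisible(x)
}

#' @export
dim.umi_counts <- function(x) dim(x$counts)

#' Subset a UMI container to given cells
#' @param x A [umi_counts()] object.
#' @param cell_ids Character vector of cell barcodes to keep (order preserved).
#' @return A `umi_counts` with only those cells.
#' @export
subset_cells <- function(x, cell_ids) {
  stopifnot(inherits(x, "umi_counts"))
  missing <- setdiff(cell_ids, colnames(x$counts))
  if (length(missing)) data_error("unknown cells: %s", paste(utils::head(missing, 5), collapse = ", "))
  keep <- match(cell_ids, x$cells$cell)
  umi_counts(x$counts[, cell_ids, drop = FALSE], x$genes, x$cells[keep, ])
}

#' Counts-per-10k normalization
#'
#' Scales each cell's counts to a common depth of 10,000 UMIs (linear scale;
#' apply `log1p()` for log-normalized values). Cells with zero total counts
#' normalize to all zeros.
#'
#' @param x A [umi_counts()] object or a gene-by-cell sparse matrix.
#' @return A `dgCMatrix` of normalized expression.
#' @export
normalize_cp10k <- function(x) {
  m <- if (inherits(x, "umi_counts")) x$counts else as(x, "CsparseMatrix")
  tot <- Matrix::colSums(m)
  scale <- ifelse(tot > 0, 1e4 / tot, 0)
  m %*% Matrix::Diagonal(x = scale, n = ncol(m)) |>
    as("CsparseMatrix") |>
    `dimnames<-`(dimnames(m))
}
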