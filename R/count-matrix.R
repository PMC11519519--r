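#' Sparse cell-by-gene count matrix
#'
#' Container for raw scRNA-seq counts with cells as rows and genes as
#' columns. Values are stored as a sparse `dgCMatrix`; entries must be
#' nonnegative integers and both identifier axes must be unique.
#'
#' @param values numeric matrix or `Matrix` sparse matrix, cells x genes,
#'   nonnegative integral entries.
#' @param cell_ids character vector of unique cell identifiers (one per row).
#'   Defaults to `cell_1 ... cell_M`.
#' @param gene_names character vector of unique gene names (one per column).
#'   Defaults to `gene_1 ... gene_N`.
#' @param meta named list of free-form provenance tags (source file, applied
#'   filters, generator parameters).
#'
#' @return An object of class `count_matrix` with fields `values`
#'   (`dgCMatrix`), `cell_ids`, `gene_names` and `meta`.
#' @export
count_matrix <- function(values, cell_ids = NULL, gene_names = NULL,
                         meta = list()) {
  if (!methods::is(values, "Matrix")) {
    values <- Matrix::Matrix(values, sparse = TRUE)
  }
  values <- methods::as(methods::as(methods::as(values, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(values@x < 0)) {
    stop("count matrix entries must be nonnegative")
  }
  if (any(values@x != round(values@x))) {
    stop("count matrix entries must be integral")
  }
  cell_ids <- as.character(cell_ids %||% paste0("cell_", seq_len(nrow(values))))
  gene_names <- as.character(gene_names %||% paste0("gene_", seq_len(ncol(values))))
  if (length(cell_ids) != nrow(values)) {
    stop("length(cell_ids) must equal the number of rows")
  }
  if (length(gene_names) != ncol(values)) {
    stop("length(gene_names) must equal the number of columns")
  }
  check_unique_ids(cell_ids, "cell_ids")
  check_unique_ids(gene_names, "gene_names")
  dimnames(values) <- list(cell_ids, gene_names)
  structure(
    list(values = Matrix::drop0(values), cell_ids = cell_ids,
         gene_names = gene_names, meta = meta),
    class = "count_matrix"
  )
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("identifier collision in %s: %s", what,
                 paste(utils::head(dup, 10), collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  nz <- length(x$values@x)
  cat(sprintf("count_matrix: %d cells x %d genes, %d nonzeros (sparsity %.3f)\n",
              nrow(x$values), ncol(x$values), nz,
              1 - nz / prod(dim(x$values))))
  if (length(x$meta)) {
    cat("meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Total gene counts (TGC) per cell
#'
#' Sum of all counts in each cell; its variability across cells reflects
#' sequencing-depth differences.
#'
#' @param cm a [count_matrix()].
#' @return numeric vector, one value per cell.
#' @export
total_counts <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  Matrix::rowSums(cm$values)
}

#' Quality-control filtering of cells and genes
#'
#' Removes low-coverage cells (fewer than `min_genes_per_cell` expressed
#' genes), cells with a high mitochondrial-count fraction, and then genes
#' expressed in fewer than `min_cells_per_gene` of the surviving cells.
#' "Expressed" means a strictly positive count. Cells are filtered first on
#' the original gene set; the gene filter is applied on surviving cells
#' only, so a second application with the same thresholds is a no-op.
#'
#' @param cm a [count_matrix()].
#' @param min_genes_per_cell minimum number of expressed genes a cell must
#'   have to be kept (default 200).
#' @param min_cells_per_gene minimum number of kept cells a gene must be
#'   expressed in (default 15).
#' @param max_mito_fraction maximum allowed fraction of a cell's counts
#'   coming from mitochondrial genes (default 0.05), computed on raw counts.
#' @param mito_prefixes case-insensitive gene-name prefixes identifying
#'   mitochondrial genes (default `c("MT-", "mt-")`).
#'
#' @return A filtered `count_matrix`; `meta$qc` records the thresholds and
#'   the number of cells/genes removed per criterion.
#' @export
qc_filter <- function(cm, min_genes_per_cell = 200, min_cells_per_gene = 15,
                      max_mito_fraction = 0.05,
                      mito_prefixes = c("MT-", "mt-")) {
  stopifnot(inherits(cm, "count_matrix"))
  x <- cm$values
  genes_per_cell <- Matrix::rowSums(x > 0)
  mito <- rep(FALSE, ncol(x))
  for (p in unique(tolower(mito_prefixes))) {
    mito <- mito | startsWith(tolower(cm$gene_names), p)
  }
  tgc <- Matrix::rowSums(x)
  mito_frac <- if (any(mito)) {
    as.numeric(Matrix::rowSums(x[, mito, drop = FALSE])) / pmax(tgc, 1)
  } else {
    numeric(nrow(x))
  }
  low_cov <- genes_per_cell < min_genes_per_cell
  high_mito <- mito_frac > max_mito_fraction
  keep_cells <- !(low_cov | high_mito)
  if (!any(keep_cells)) {
    stop("qc_filter removed all cells; check thresholds against this dataset")
  }
  xs <- x[keep_cells, , drop = FALSE]
  cells_per_gene <- Matrix::colSums(xs > 0)
  keep_genes <- cells_per_gene >= min_cells_per_gene
  qc <- list(
    min_genes_per_cell = min_genes_per_cell,
    min_cells_per_gene = min_cells_per_gene,
    max_mito_fraction = max_mito_fraction,
    mito_prefixes = mito_prefixes,
    order = "cells_then_genes",
    cells_removed_low_coverage = sum(low_cov),
    cells_removed_mito = sum(high_mito & !low_cov),
    genes_removed = sum(!keep_genes)
  )
  count_matrix(
    xs[, keep_genes, drop = FALSE],
    cell_ids = cm$cell_ids[keep_cells],
    gene_names = cm$gene_names[keep_genes],
    meta = c(cm$meta, list(qc = qc))
  )
}
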