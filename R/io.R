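#' Read a count matrix from disk
#'
#' Supports the 10x Genomics Matrix-Market triplet layout (`matrix.mtx(.gz)`
#' plus `barcodes.tsv(.gz)` and `features.tsv(.gz)`/`genes.tsv(.gz)` in one
#' directory), dense CSV/TSV with cell rows, and an HDF5 container with
#' datasets `/values` (COO triplets), `/cell_ids` and `/gene_names`.
#' 10x matrices are stored genes x cells on disk and are transposed on load
#' so that the returned matrix is always cells x genes.
#'
#' @param path directory (for `mtx10x`) or file path.
#' @param fmt one of `"mtx10x"`, `"csv"`, `"h5"`.
#' @return A [count_matrix()]; `meta$source` records the path and format.
#' @export
read_counts <- function(path, fmt = c("mtx10x", "csv", "h5")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("path does not exist: ", path)
  cm <- switch(fmt,
    mtx10x = read_counts_mtx10x(path),
    csv = read_counts_csv(path),
    h5 = read_counts_h5(path)
  )
  cm$meta$source <- list(path = path, format = fmt)
  cm
}

find_companion <- function(dir, stems) {
  for (s in stems) {
    for (ext in c("", ".gz")) {
      f <- file.path(dir, paste0(s, ext))
      if (file.exists(f)) return(f)
    }
  }
  stop("missing companion file in ", dir, ": expected one of ",
       paste(stems, collapse = ", "))
}

read_counts_mtx10x <- function(dir) {
  if (!dir.exists(dir)) stop("mtx10x format expects a directory: ", dir)
  mtx <- find_companion(dir, c("matrix.mtx"))
  bc <- find_companion(dir, c("barcodes.tsv"))
  ft <- find_companion(dir, c("features.tsv", "genes.tsv"))
  m <- Matrix::readMM(mtx) # genes x cells on disk
  barcodes <- utils::read.table(bc, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[, 1]
  feat <- utils::read.table(ft, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
  # second column holds the gene symbol when present (10x convention)
  symbols <- if (ncol(feat) >= 2) feat[, 2] else feat[, 1]
  symbols <- dedup_names(symbols)
  count_matrix(Matrix::t(m), cell_ids = barcodes, gene_names = symbols)
}

# Suffix "-1", "-2", ... onto repeated names, keeping first occurrences.
dedup_names <- function(x) {
  x <- as.character(x)
  dup <- duplicated(x)
  if (any(dup)) {
    message(sum(dup), " duplicated gene name(s) de-duplicated by suffixing")
    x <- make.unique(x, sep = "-")
  }
  x
}

read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cell_ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (any(!is.finite(vals)) || any(vals != round(vals))) {
    stop("non-integer entries in ", path)
  }
  storage.mode(vals) <- "double"
  count_matrix(vals, cell_ids = cell_ids, gene_names = colnames(df)[-1])
}

read_counts_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("the h5 format requires the rhdf5 package")
  }
  i <- as.integer(rhdf5::h5read(path, "values/i"))
  j <- as.integer(rhdf5::h5read(path, "values/j"))
  x <- as.numeric(rhdf5::h5read(path, "values/x"))
  dims <- as.integer(rhdf5::h5read(path, "values/dims"))
  cell_ids <- as.character(rhdf5::h5read(path, "cell_ids"))
  gene_names <- as.character(rhdf5::h5read(path, "gene_names"))
  m <- Matrix::sparseMatrix(i = i + 1L, j = j + 1L, x = x,
                            dims = dims, repr = "C")
  count_matrix(m, cell_ids = cell_ids, gene_names = gene_names)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]: the written file(s) can be read back with the
#' same `fmt`, reproducing values and identifiers exactly.
#'
#' @param cm a [count_matrix()].
#' @param path output directory (`mtx10x`) or file path (`csv`, `h5`).
#' @param fmt one of `"mtx10x"`, `"csv"`, `"h5"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, fmt = c("mtx10x", "csv", "h5")) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(cm, "count_matrix"))
  switch(fmt,
    mtx10x = {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      m <- Matrix::t(cm$values) # genes x cells on disk, 10x convention
      Matrix::writeMM(m, file.path(path, "matrix.mtx"))
      writeLines(cm$cell_ids, file.path(path, "barcodes.tsv"))
      utils::write.table(
        data.frame(id = cm$gene_names, symbol = cm$gene_names,
                   type = "Gene Expression"),
        file.path(path, "features.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    },
    csv = {
      df <- data.frame(cell_id = cm$cell_ids, as.matrix(cm$values),
                       check.names = FALSE)
      colnames(df) <- c("cell_id", cm$gene_names)
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    },
    h5 = {
      if (!requireNamespace("rhdf5", quietly = TRUE)) {
        stop("the h5 format requires the rhdf5 package")
      }
      if (file.exists(path)) file.remove(path)
      rhdf5::h5createFile(path)
      tr <- methods::as(cm$values, "TsparseMatrix")
      rhdf5::h5createGroup(path, "values")
      rhdf5::h5write(tr@i, path, "values/i")
      rhdf5::h5write(tr@j, path, "values/j")
      rhdf5::h5write(tr@x, path, "values/x")
      rhdf5::h5write(dim(cm$values), path, "values/dims")
      rhdf5::h5write(cm$cell_ids, path, "cell_ids")
      rhdf5::h5write(cm$gene_names, path, "gene_names")
      rhdf5::h5closeAll()
    }
  )
  invisible(path)
}

#' Read cell labels from a CSV file
#'
#' Accepts a single-column file (labels in matrix cell order) or a
#' two-column `(cell_id, label)` file; with `cell_ids` supplied the labels
#' are reordered to match.
#'
#' @param path CSV file path.
#' @param cell_ids optional character vector to align a two-column file to.
#' @return character vector of labels.
#' @export
read_labels <- function(path, cell_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) == 1) {
    return(as.character(df[[1]]))
  }
  labels <- as.character(df[[2]])
  names(labels) <- as.character(df[[1]])
  if (!is.null(cell_ids)) {
    missing <- setdiff(cell_ids, names(labels))
    if (length(missing)) {
      stop("labels missing for cells: ", paste(utils::head(missing, 5), collapse = ", "))
    }
    labels <- labels[cell_ids]
  }
  unname(labels)
}
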