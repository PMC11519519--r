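#' Normalized expression matrix
#'
#' Real-valued cells x genes matrix together with the ordered record of the
#' transforms that produced it. Values may be stored dense or sparse; the
#' `steps` list is append-only and fully determines the transform.
#'
#' @param values numeric matrix (base or `Matrix`), cells x genes.
#' @param cell_ids,gene_names identifiers carried through from the counts.
#' @param steps list of applied transform records.
#' @return An object of class `normalized_matrix`.
#' @keywords internal
normalized_matrix <- function(values, cell_ids, gene_names, steps = list()) {
  structure(
    list(values = values, cell_ids = cell_ids, gene_names = gene_names,
         steps = steps),
    class = "normalized_matrix"
  )
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d cells x %d genes\n",
              nrow(x$values), ncol(x$values)))
  cat("steps:", paste(vapply(x$steps, function(s) s$step, ""), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Log normalization of raw counts
#'
#' Divides each cell by its total gene count (TGC), multiplies by the
#' scaling factor `L` and applies `log(1 + x)`:
#' entry (i,j) becomes `log(1 + L * X_ij / TGC_i)`. Zeros map to zeros, so
#' sparsity is preserved and sparse storage is kept. The conventional
#' Seurat/Scanpy choice is `L = 10000`; here the default is `L = 1`, which
#' keeps the nonzero entries on a scale comparable across sequencing
#' depths.
#'
#' @param cm a [count_matrix()].
#' @param L positive scaling factor (default 1).
#' @return A `normalized_matrix` with one recorded step.
#' @export
log_normalize <- function(cm, L = 1) {
  stopifnot(inherits(cm, "count_matrix"), L > 0)
  tgc <- total_counts(cm)
  if (any(tgc <= 0)) {
    stop("cells with zero total counts present (cells: ",
         paste(utils::head(cm$cell_ids[tgc <= 0], 5), collapse = ", "),
         "); run qc_filter first")
  }
  v <- Matrix::Diagonal(x = L / tgc) %*% cm$values
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  normalized_matrix(v, cm$cell_ids, cm$gene_names,
                    steps = list(list(step = "log", L = L)))
}

# Column medians of a sparse matrix without densifying: a column whose
# zeros reach strictly past the middle positions has median 0.
sparse_col_medians <- function(v) {
  m <- nrow(v)
  meds <- numeric(ncol(v))
  p <- v@p
  for (j in seq_len(ncol(v))) {
    nz <- p[j + 1L] - p[j]
    if (2L * nz < m) next # both middle order statistics are zeros
    xs <- v@x[(p[j] + 1L):p[j + 1L]]
    col <- c(numeric(m - nz), sort(xs)) # nonzeros are >= 0 post log1p
    meds[j] <- stats::median(col)
  }
  meds
}

#' Gene-wise scaling of log-normalized expression
#'
#' Centers each gene (column) by its mean or median and divides by its
#' standard deviation. The standard deviation uses the population
#' (divide-by-n) convention and is the same for both centering choices.
#' Median centering is the memory-saving variant: when a gene's median is 0
#' (the typical sparse case) its zero entries stay zero, so sparse storage
#' is retained. Zero-variance genes are set to 0 with a warning rather than
#' dropped, so the gene count entering the Gram normalization is unchanged.
#'
#' @param nm a `normalized_matrix` from [log_normalize()].
#' @param center `"mean"` (classical z-score) or `"median"`.
#' @return A `normalized_matrix` with the scaling step appended.
#' @export
gene_scale <- function(nm, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(inherits(nm, "normalized_matrix"))
  v <- nm$values
  m <- nrow(v)
  if (m < 2) stop("gene scaling requires at least 2 cells")
  mu_mean <- as.numeric(Matrix::colMeans(v))
  ex2 <- as.numeric(Matrix::colMeans(v * v))
  sigma <- sqrt(pmax(ex2 - mu_mean^2, 0))
  zero_var <- sigma <= 1e-12
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance gene(s) set to 0 after scaling")
  }
  sigma_safe <- ifelse(zero_var, 1, sigma)
  mu <- if (center == "mean") mu_mean else sparse_col_medians(methods::as(v, "CsparseMatrix"))
  mu[zero_var] <- 0
  if (center == "median" && all(mu == 0)) {
    # pure sparse path: only a per-column rescale
    out <- methods::as(v %*% Matrix::Diagonal(x = 1 / sigma_safe), "CsparseMatrix")
    if (any(zero_var)) out[, zero_var] <- 0
    out <- Matrix::drop0(out)
  } else {
    out <- sweep(sweep(as.matrix(v), 2, mu, "-"), 2, sigma_safe, "/")
    out[, zero_var] <- 0
  }
  normalized_matrix(out, nm$cell_ids, nm$gene_names,
                    steps = c(nm$steps, list(list(step = "scale", center = center,
                                                  sd = "population"))))
}

#' L2 normalization of cell vectors
#'
#' Divides each cell (row) by its Euclidean norm so that every cell vector
#' has unit length. This removes the cell-vector-length differences that
#' log normalization leaves behind for cells of different sequencing depth,
#' which would otherwise inflate the Gram-matrix diagonal of low-depth
#' cells and create artificial signal eigenvalues.
#'
#' @param nm a `normalized_matrix`.
#' @return A `normalized_matrix` whose rows all have norm 1.
#' @export
l2_normalize <- function(nm) {
  stopifnot(inherits(nm, "normalized_matrix"))
  v <- nm$values
  norms <- sqrt(as.numeric(Matrix::rowSums(v * v)))
  bad <- norms <= 0
  if (any(bad)) {
    stop("zero-norm cell vector(s): ",
         paste(utils::head(nm$cell_ids[bad], 5), collapse = ", "))
  }
  out <- Matrix::Diagonal(x = 1 / norms) %*% v
  if (!methods::is(nm$values, "Matrix")) out <- as.matrix(out)
  normalized_matrix(out, nm$cell_ids, nm$gene_names,
                    steps = c(nm$steps, list(list(step = "l2"))))
}

#' Full preprocessing: log normalization, gene scaling, L2 normalization
#'
#' Applies [log_normalize()], [gene_scale()] and (optionally)
#' [l2_normalize()] in that order. `l2 = FALSE` reproduces the conventional
#' log-normalization pipeline used as the distortion baseline.
#'
#' @param cm a [count_matrix()] (post-QC).
#' @param L scaling factor for log normalization (default 1).
#' @param center `"mean"` or `"median"` gene centering.
#' @param l2 apply L2 cell normalization (default `TRUE`).
#' @return A `normalized_matrix` with all steps recorded.
#' @export
preprocess <- function(cm, L = 1, center = c("mean", "median"), l2 = TRUE) {
  center <- match.arg(center)
  nm <- gene_scale(log_normalize(cm, L = L), center = center)
  if (l2) nm <- l2_normalize(nm)
  nm
}
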