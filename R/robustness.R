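#' Sparse binary perturbation of a count matrix
#'
#' Adds a binary random matrix `B` to the counts, each entry of `B` being
#' 1 independently with probability `1 - sparsity`. The original matrix is
#' unmodified; the result is deterministic given `seed`.
#'
#' @param cm a [count_matrix()].
#' @param sparsity fraction of zero entries in the perturbation matrix,
#'   in (0,1); typical values are 0.97 and above.
#' @param seed integer RNG seed.
#' @return A perturbed `count_matrix`.
#' @export
perturb_counts <- function(cm, sparsity, seed) {
  stopifnot(inherits(cm, "count_matrix"), sparsity > 0, sparsity < 1)
  m <- nrow(cm$values); n <- ncol(cm$values)
  total <- as.numeric(m) * n
  with_seed(seed, {
    n_ones <- stats::rbinom(1, size = total, prob = 1 - sparsity)
    if (n_ones == 0) {
      v <- cm$values
    } else {
      pos <- sample(total, n_ones) # positions in column-major order
      b <- Matrix::sparseMatrix(
        i = as.integer((pos - 1) %% m) + 1L,
        j = as.integer((pos - 1) %/% m) + 1L,
        x = 1, dims = c(m, n), repr = "C")
      v <- cm$values + b
    }
    count_matrix(v, cm$cell_ids, cm$gene_names,
                 meta = c(cm$meta, list(perturbation = list(
                   sparsity = sparsity, seed = seed, n_added = n_ones))))
  })
}

#' Binarize a count matrix
#'
#' Replaces every nonzero count with 1, leaving the zero pattern intact.
#' Used to isolate the zero-pattern (binary) information when selecting
#' the perturbation sparsity.
#'
#' @param cm a [count_matrix()].
#' @return A binary `count_matrix` with the same nonzero pattern.
#' @export
binarize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  v <- cm$values
  v@x <- rep(1, length(v@x))
  count_matrix(v, cm$cell_ids, cm$gene_names, meta = cm$meta)
}

# Eigenvectors used by the sparsity-selection comparisons: the signal
# vectors when any exceed the TW threshold, otherwise the leading
# `fallback` eigenvectors.
selection_vectors <- function(cm, L, center, l2, alpha = 0.05, fallback = 5) {
  nm <- preprocess(cm, L = L, center = center, l2 = l2)
  spec <- full_spectrum(nm)
  fit <- try(fit_marchenko_pastur(spec), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    thr <- tracy_widom_threshold(fit, spec$n_cells, spec$n_genes, alpha)
    idx <- which(spec$values > thr)
    if (length(idx) > 0) {
      return(spec$vectors[, idx, drop = FALSE])
    }
  }
  spec$vectors[, seq_len(min(fallback, ncol(spec$vectors))), drop = FALSE]
}

# Column-wise best absolute match of `va`'s vectors in `vb`.
best_matches <- function(vb, va) {
  apply(abs(crossprod(vb, va)), 2, max)
}

#' Select the perturbation sparsity for the robustness test
#'
#' Iterative procedure on the binarized data: starting from a very sparse
#' perturbation (`start`), the sparsity is gradually lowered; at each
#' level the binarized matrix and its perturbed version are preprocessed,
#' their eigenvector sets compared, and the minimum best-match correlation
#' across the reference vectors computed. The loop stops once that
#' minimum falls below the baseline correlation observed between two
#' unrelated random binary matrices of the data's own sparsity, and the
#' last level before the drop is returned. The selected level is the
#' strongest perturbation that still preserves the data's zero-pattern
#' structure; on structured data it typically stays at 0.97 or above.
#'
#' @param cm a [count_matrix()] (post-QC).
#' @param start initial sparsity (default 0.999).
#' @param step decrement per iteration (default 0.001).
#' @param floor lowest sparsity attempted before giving up (default 0.9).
#' @param seed integer master seed.
#' @param L,center,l2 preprocessing settings (defaults `1`, `"mean"`,
#'   `TRUE`).
#' @param n_baseline number of independent random-matrix pairs averaged
#'   for the baseline correlation (default 3).
#' @return Selected sparsity level, with the correlation trajectory in
#'   attribute `"trajectory"` and the baseline in attribute `"baseline"`.
#' @export
select_perturbation_sparsity <- function(cm, start = 0.999, step = 0.001,
                                         floor = 0.9, seed = 1,
                                         L = 1, center = "mean", l2 = TRUE,
                                         n_baseline = 3) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- nrow(cm$values); n <- ncol(cm$values)
  total <- as.numeric(m) * n
  data_sparsity <- 1 - length(cm$values@x) / total
  seeds <- spawn_seeds(seed, 4 * n_baseline + 3000)
  bin <- binarize(cm)
  vref <- selection_vectors(bin, L, center, l2)
  # null correlation scale: best match of the leading vectors of a random
  # binary matrix at the data's own sparsity against the full eigenvector
  # set of a second, unrelated random matrix at the perturbed matrix's
  # sparsity -- the same comparison the loop makes, so a reference vector
  # whose structure is destroyed lands at this level
  null_corr <- function(pert_sparsity, b) {
    r1 <- random_binary_cm(m, n, data_sparsity, seeds[4 * b - 3])
    r2 <- random_binary_cm(m, n, pert_sparsity, seeds[4 * b - 2])
    v1 <- selection_vectors(r1, L, center, l2)
    v2 <- full_spectrum(preprocess(r2, L = L, center = center, l2 = l2))$vectors
    mean(best_matches(v2, v1))
  }
  levels <- seq(start, floor, by = -step)
  traj <- numeric(0)
  base_traj <- numeric(0)
  prev <- start
  for (k in seq_along(levels)) {
    s <- levels[k]
    pert <- perturb_counts(bin, s, seeds[4 * n_baseline + k])
    pert_sparsity <- 1 - length(pert$values@x) / total
    vp <- full_spectrum(preprocess(pert, L = L, center = center, l2 = l2))$vectors
    min_corr <- min(best_matches(vp, vref))
    baseline <- mean(vapply(seq_len(n_baseline), function(b) {
      null_corr(pert_sparsity, b)
    }, numeric(1)))
    traj <- c(traj, min_corr)
    base_traj <- c(base_traj, baseline)
    if (min_corr < baseline) {
      out <- prev
      attr(out, "trajectory") <- stats::setNames(traj, levels[seq_len(k)])
      attr(out, "baseline") <- stats::setNames(base_traj, levels[seq_len(k)])
      return(out)
    }
    prev <- s
  }
  stop(sprintf(
    "sparsity selection exhausted candidates down to %.3f without the minimum correlation (last %.3f) dropping below the baseline (last %.3f)",
    floor, traj[length(traj)], base_traj[length(base_traj)]))
}

random_binary_cm <- function(m, n, sparsity, seed) {
  with_seed(seed, {
    total <- as.numeric(m) * n
    n_ones <- stats::rbinom(1, size = total, prob = 1 - sparsity)
    n_ones <- max(n_ones, 1)
    pos <- sample(total, n_ones)
    count_matrix(Matrix::sparseMatrix(
      i = as.integer((pos - 1) %% m) + 1L,
      j = as.integer((pos - 1) %/% m) + 1L,
      x = 1, dims = c(m, n), repr = "C"))
  })
}

#' Score signal robustness under sparse perturbation
#'
#' Generates `K` perturbed count matrices, preprocesses each identically
#' to the original, computes the full eigenvector set of each perturbed
#' Gram matrix, and for every original signal vector records its best
#' absolute inner product with any perturbed eigenvector. A signal's
#' robustness is the mean of its `K` best matches: near 1 for stable
#' signal directions, low for dropout-driven components that a slight
#' perturbation of the zero pattern destroys.
#'
#' @param cm the post-QC [count_matrix()] the signals were derived from.
#' @param signals a `signal_set` obtained from `cm` under the same
#'   preprocessing settings.
#' @param sparsity perturbation sparsity, e.g. from
#'   [select_perturbation_sparsity()].
#' @param K number of perturbation replicates (default 10; must be >= 2).
#' @param seed integer master seed (ignored when `seeds` is given).
#' @param seeds optional vector of `K` per-replicate seeds.
#' @param L,center,l2 preprocessing settings (must match those used for
#'   `signals`).
#' @return An object of class `robustness_report`: `robustness` (one value
#'   in \[0,1\] per signal), `per_replicate` (K x n_signals matrix of best
#'   matches), `perturbation_sparsity`, `K`, `seeds`.
#' @export
signal_robustness <- function(cm, signals, sparsity, K = 10, seed = 1,
                              seeds = NULL, L = 1, center = "mean",
                              l2 = TRUE) {
  stopifnot(inherits(cm, "count_matrix"), inherits(signals, "signal_set"))
  if (K < 2) stop("K must be at least 2: robustness is a mean over replicates")
  if (is.null(seeds)) seeds <- spawn_seeds(seed, K)
  if (length(seeds) != K) stop("length(seeds) must equal K")
  ns <- n_signals(signals)
  per_replicate <- matrix(NA_real_, nrow = K, ncol = ns)
  for (i in seq_len(K)) {
    pert <- perturb_counts(cm, sparsity, seeds[i])
    vp <- full_spectrum(preprocess(pert, L = L, center = center, l2 = l2))$vectors
    per_replicate[i, ] <- best_matches(vp, signals$vectors)
  }
  out <- list(robustness = colMeans(per_replicate),
              per_replicate = per_replicate,
              perturbation_sparsity = sparsity, K = K, seeds = seeds)
  class(out) <- "robustness_report"
  out
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness_report: %d signal(s), K = %d, sparsity = %.4f\n",
              length(x$robustness), x$K, x$perturbation_sparsity))
  print(round(x$robustness, 3))
  invisible(x)
}

#' Keep only robust signals
#'
#' Subsets a `signal_set` to the signals whose robustness is strictly
#' greater than `threshold` (default 0.5), preserving order.
#'
#' @param signals a `signal_set`.
#' @param report the matching `robustness_report`.
#' @param threshold robustness cutoff (default 0.5).
#' @return A `signal_set` containing the robust signals only.
#' @export
select_robust <- function(signals, report, threshold = 0.5) {
  stopifnot(inherits(signals, "signal_set"),
            inherits(report, "robustness_report"))
  if (length(report$robustness) != n_signals(signals)) {
    stop("robustness report is not aligned to the signal set")
  }
  keep <- report$robustness > threshold
  if (!any(keep)) {
    warning("no signal passed the robustness threshold ", threshold)
  }
  out <- list(indices = signals$indices[keep],
              eigenvalues = signals$eigenvalues[keep],
              vectors = signals$vectors[, keep, drop = FALSE],
              tw_threshold = signals$tw_threshold,
              mp_fit = signals$mp_fit,
              cell_ids = signals$cell_ids,
              robustness = report$robustness[keep])
  class(out) <- "signal_set"
  out
}
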