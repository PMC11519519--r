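#' Pure-noise Poisson count block
#'
#' Dense random matrix with i.i.d. Poisson entries; the canonical
#' pure-noise control whose Gram spectrum should show no signal.
#'
#' @param m,n number of cells and genes (defaults 2000 x 2000).
#' @param lam Poisson mean (default 2).
#' @param seed integer RNG seed.
#' @return A [count_matrix()].
#' @export
poisson_block <- function(m = 2000, n = 2000, lam = 2, seed = 1) {
  stopifnot(m >= 2, n >= 2, lam > 0)
  with_seed(seed, {
    count_matrix(matrix(stats::rpois(m * n, lam), nrow = m),
                 meta = list(generator = list(kind = "poisson_block", m = m,
                                              n = n, lam = lam, seed = seed)))
  })
}

#' Sparse binary count block
#'
#' Random matrix with i.i.d. Bernoulli(1 - sparsity) entries, emulating
#' the highly sparse portion of scRNA-seq count data.
#'
#' @param m,n number of cells and genes (defaults 2000 x 8000).
#' @param sparsity fraction of zeros, in (0,1).
#' @param seed integer RNG seed.
#' @return A [count_matrix()] with values in \{0, 1\}.
#' @export
sparse_binary_block <- function(m = 2000, n = 8000, sparsity = 0.95, seed = 1) {
  stopifnot(sparsity > 0, sparsity < 1)
  with_seed(seed, {
    total <- as.numeric(m) * n
    n_ones <- stats::rbinom(1, size = total, prob = 1 - sparsity)
    v <- if (n_ones == 0) {
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(m, n), repr = "C")
    } else {
      pos <- sample(total, n_ones)
      Matrix::sparseMatrix(i = as.integer((pos - 1) %% m) + 1L,
                           j = as.integer((pos - 1) %/% m) + 1L,
                           x = 1, dims = c(m, n), repr = "C")
    }
    count_matrix(v, meta = list(generator = list(kind = "sparse_binary", m = m,
                                                 n = n, sparsity = sparsity,
                                                 seed = seed)))
  })
}

#' Depth-biased noise dataset
#'
#' Concatenates a dense Poisson block with a sparse binary block and then
#' multiplies the first `bias_rows` rows of the dense part by
#' `bias_factor` (rounding half to even to stay integral). The result is
#' a pure-noise matrix containing a group of low-TGC cells. Conventional
#' log normalization inflates the Gram diagonal of those cells and
#' produces about `bias_rows` artificial signal eigenvalues; L2
#' normalization removes them.
#'
#' @param seed integer RNG seed.
#' @param bias_rows number of cells whose dense counts are scaled
#'   (default 400).
#' @param bias_factor multiplicative depth bias (default 0.5).
#' @param m total number of cells (default 2000).
#' @param n_dense,n_sparse gene counts of the dense and sparse blocks
#'   (defaults 2000 and 8000).
#' @param lam Poisson mean of the dense block (default 2).
#' @param sparsity sparsity of the binary block (default 0.95).
#' @param bias_mode `"round"` (scale and round half to even, the default)
#'   or `"redraw"` (redraw the biased rows from Poisson with scaled mean).
#' @return A [count_matrix()] of size `m x (n_dense + n_sparse)`.
#' @export
tgc_biased_dataset <- function(seed = 1, bias_rows = 400, bias_factor = 0.5,
                               m = 2000, n_dense = 2000, n_sparse = 8000,
                               lam = 2, sparsity = 0.95,
                               bias_mode = c("round", "redraw")) {
  bias_mode <- match.arg(bias_mode)
  stopifnot(bias_rows < m)
  seeds <- spawn_seeds(seed, 3)
  dense <- poisson_block(m, n_dense, lam, seeds[1])
  sparse <- sparse_binary_block(m, n_sparse, sparsity, seeds[2])
  dv <- as.matrix(dense$values)
  rows <- seq_len(bias_rows)
  if (bias_mode == "round") {
    dv[rows, ] <- round(dv[rows, ] * bias_factor)
  } else {
    dv[rows, ] <- with_seed(seeds[3], {
      matrix(stats::rpois(bias_rows * n_dense, lam * bias_factor),
             nrow = bias_rows)
    })
  }
  v <- cbind(methods::as(dv, "CsparseMatrix"), sparse$values)
  count_matrix(v, meta = list(generator = list(
    kind = "tgc_biased", seed = seed, bias_rows = bias_rows,
    bias_factor = bias_factor, m = m, n_dense = n_dense,
    n_sparse = n_sparse, lam = lam, sparsity = sparsity,
    bias_mode = bias_mode)))
}

#' Planted-cluster gamma-Poisson counts
#'
#' Simulates `k` cell populations with negative-binomial (gamma-Poisson)
#' counts: lognormal per-gene base means, a disjoint set of
#' differentially expressed genes per cluster (up-scaled by `effect`),
#' lognormal per-cell size factors with coefficient of variation
#' `tgc_cv`, and a global scale tuned so the expected zero fraction
#' matches `target_sparsity`. With `effect = 1` the design collapses to a
#' label-free null.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param k number of clusters (>= 2).
#' @param de_fraction fraction of genes differentially expressed per
#'   cluster (disjoint across clusters).
#' @param effect fold-change of DE genes (1 = null); either a scalar or a
#'   vector of length `k` giving each cluster its own effect size, so
#'   designs can mix strong and marginal populations.
#' @param tgc_cv coefficient of variation of cell size factors.
#' @param target_sparsity desired overall zero fraction in (0,1).
#' @param dispersion gamma-Poisson dispersion (default 0.1); 0 gives pure
#'   Poisson sampling.
#' @param seed integer RNG seed.
#' @return List with elements `counts` (a [count_matrix()]) and `labels`
#'   (character vector of cluster memberships).
#' @export
planted_clusters <- function(n_cells = 500, n_genes = 1000, k = 3,
                             de_fraction = 0.1, effect = 4, tgc_cv = 0.3,
                             target_sparsity = 0.6, dispersion = 0.1,
                             seed = 1) {
  stopifnot(k >= 2, de_fraction >= 0, de_fraction * k <= 1, all(effect > 0),
            target_sparsity > 0, target_sparsity < 1)
  effect <- rep_len(effect, k)
  with_seed(seed, {
    labels <- paste0("cluster_", rep_len(seq_len(k), n_cells))
    base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    fold <- matrix(1, nrow = k, ncol = n_genes)
    n_de <- floor(de_fraction * n_genes)
    de_pool <- sample(n_genes, n_de * k)
    for (c in seq_len(k)) {
      fold[c, de_pool[((c - 1) * n_de + 1):(c * n_de)]] <- effect[c]
    }
    sdlog <- sqrt(log(1 + tgc_cv^2))
    size_f <- stats::rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    cluster_idx <- rep_len(seq_len(k), n_cells)
    mu0 <- (size_f %o% base) * fold[cluster_idx, , drop = FALSE]
    # tune global scale so the expected zero fraction hits the target
    expected_zero <- function(a) {
      mu <- a * mu0
      if (dispersion > 0) {
        mean((1 + dispersion * mu)^(-1 / dispersion))
      } else {
        mean(exp(-mu))
      }
    }
    f <- function(loga) expected_zero(exp(loga)) - target_sparsity
    scale_a <- exp(stats::uniroot(f, interval = c(-15, 15))$root)
    mu <- scale_a * mu0
    counts <- if (dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    cm <- count_matrix(matrix(counts, nrow = n_cells),
                       meta = list(generator = list(
                         kind = "planted_clusters", n_cells = n_cells,
                         n_genes = n_genes, k = k, de_fraction = de_fraction,
                         effect = effect, tgc_cv = tgc_cv,
                         target_sparsity = target_sparsity,
                         dispersion = dispersion, seed = seed,
                         scale = scale_a)))
    list(counts = cm, labels = labels)
  })
}
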