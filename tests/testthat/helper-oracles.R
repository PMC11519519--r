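# Shared fixtures and independent oracles used across test files.

# Random sparse integer count matrix with unique ids.
random_counts <- function(m, n, density = 0.2, max_count = 20, seed = 1) {
  withr::with_seed(seed, {
    nnz <- rbinom(1, m * n, density)
    pos <- sample(m * n, nnz)
    v <- Matrix::sparseMatrix(
      i = (pos - 1) %% m + 1, j = (pos - 1) %/% m + 1,
      x = sample.int(max_count, nnz, replace = TRUE), dims = c(m, n),
      repr = "C")
    count_matrix(v, cell_ids = sprintf("c%03d", seq_len(m)),
                 gene_names = sprintf("g%03d", seq_len(n)))
  })
}

# Personalized-PageRank affinities by plain power iteration on the
# cluster-induced clique graph (self-loops included): the independent
# oracle for the closed-form affinity used by ecs().
ppr_affinity_power <- function(labels, d = 0.9, iters = 500) {
  labels <- as.character(labels)
  n <- length(labels)
  P <- matrix(0, n, n)
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    P[idx, idx] <- 1 / length(idx)
  }
  f <- matrix(0, n, n)
  for (i in seq_len(n)) {
    v <- rep(0, n); v[i] <- 1
    x <- v
    for (t in seq_len(iters)) {
      x <- (1 - d) * v + d * as.vector(x %*% P)
    }
    f[i, ] <- x
  }
  f
}

ecs_power_oracle <- function(a, b, d = 0.9) {
  fa <- ppr_affinity_power(a, d)
  fb <- ppr_affinity_power(b, d)
  mean(1 - rowSums(abs(fa - fb)) / (2 * d))
}

# Count signals of a count matrix under a given normalization, straight
# through the spectral chain.
count_signals <- function(cm, l2, center = "mean", alpha = 0.05) {
  nm <- suppressWarnings(preprocess(cm, L = 1, center = center, l2 = l2))
  sp <- full_spectrum(nm)
  fit <- fit_marchenko_pastur(sp)
  thr <- tracy_widom_threshold(fit, sp$n_cells, sp$n_genes, alpha)
  sum(sp$values > thr)
}
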