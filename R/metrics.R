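scores_of <- function(x) {
  if (inherits(x, "sc_embedding")) x$scores else as.matrix(x)
}

pairwise_dist <- function(points, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    as.matrix(stats::dist(points))
  } else {
    nrm <- sqrt(rowSums(points^2))
    if (any(nrm == 0)) stop("cosine metric undefined for zero vectors")
    s <- tcrossprod(points / nrm)
    d <- 1 - pmin(pmax(s, -1), 1)
    diag(d) <- 0
    d
  }
}

#' Mean silhouette score of a labelled embedding
#'
#' For each point, `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean
#' distance to the other members of its own cluster and `b_i` the smallest
#' mean distance to any other cluster; the score is the mean over points.
#' Values near 1 indicate compact, well-separated clusters; 0 indicates
#' overlap; negative values indicate misassignment. Members of singleton
#' clusters contribute `s_i = 0`.
#'
#' @param points numeric matrix (n x d) or `sc_embedding`.
#' @param labels vector of cluster labels, one per point (>= 2 clusters).
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @return Mean silhouette in \[-1, 1\].
#' @export
silhouette_score <- function(points, labels, metric = c("euclidean", "cosine")) {
  points <- scores_of(points)
  labels <- as.character(labels)
  stopifnot(nrow(points) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("silhouette is undefined for a single cluster")
  }
  d <- pairwise_dist(points, metric)
  n <- nrow(d)
  cl <- split(seq_len(n), labels)
  sizes <- lengths(cl)
  # mean distance from every point to every cluster
  mean_to_cluster <- vapply(cl, function(idx) {
    rowSums(d[, idx, drop = FALSE]) / length(idx)
  }, numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[own]] == 1) { s[i] <- 0; next }
    a <- mean_to_cluster[i, own] * sizes[[own]] / (sizes[[own]] - 1) # exclude self
    b <- min(mean_to_cluster[i, setdiff(names(cl), own)])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Closed-form personalized-PageRank affinity of element i under a
# clustering: restart mass (1-d) on i itself plus d spread uniformly over
# i's cluster (self included); zero elsewhere.
ecs_frame <- function(labels) {
  labels <- as.character(labels)
  sizes <- table(labels)
  list(labels = labels, sizes = as.numeric(sizes[labels]))
}

#' Element-centric similarity (ECS) of two clusterings
#'
#' Compares two cluster assignments through the personalized-PageRank
#' affinities each induces on the cluster-clique graphs: for element `i`,
#' `S_i = 1 - 1/(2d) * sum_j |f^a_ij - f^b_ij|`, and the ECS is the mean
#' of `S_i`. Unlike ARI/NMI it is not biased by cluster number or size.
#'
#' @param a,b cluster assignments of the same elements (same length).
#' @param d damping factor in (0,1), default 0.9.
#' @return ECS in \[0,1\]; 1 for identical clusterings.
#' @export
ecs <- function(a, b, d = 0.9) {
  if (length(a) != length(b)) stop("clusterings must have the same length")
  stopifnot(d > 0, d < 1)
  fa <- ecs_frame(a)
  fb <- ecs_frame(b)
  n <- length(fa$labels)
  # cross-tabulate: for element i only its two clusters overlap
  key <- paste(fa$labels, fb$labels, sep = "\r")
  inter <- table(key)[key] # |A_i intersect B_i| for each i
  inter <- as.numeric(inter)
  sa <- fa$sizes
  sb <- fb$sizes
  total_diff <- abs(d / sa - d / sb) * inter +
    (d / sa) * (sa - inter) + (d / sb) * (sb - inter)
  mean(1 - total_diff / (2 * d))
}

knn_lists <- function(points, k_max, metric) {
  d <- pairwise_dist(points, metric)
  n <- nrow(d)
  out <- matrix(0L, n, k_max)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i]) # stable: ties broken by lowest index
    idx <- seq_len(n)[-i][ord]
    out[i, ] <- idx[seq_len(k_max)]
  }
  out
}

#' Average kNN-graph overlap between two embeddings
#'
#' For each neighborhood size `k` from `k_min` to `k_max`, builds the two
#' k-nearest-neighbor graphs, counts the edges present in both (an edge
#' being a cell together with one of its k nearest neighbors), and
#' normalizes by the total neighbor count. The score is the average over
#' the `k` grid: 1 means the graphs are identical, 0 means they share no
#' edges.
#'
#' @param embA,embB embeddings (`sc_embedding` or matrices) of the same
#'   cells in the same row order.
#' @param k_min,k_max neighborhood size range (defaults 5 and 50).
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return Mean overlap in \[0,1\].
#' @export
avg_knn_overlap <- function(embA, embB, k_min = 5, k_max = 50,
                            metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  a <- scores_of(embA)
  b <- scores_of(embB)
  stopifnot(nrow(a) == nrow(b))
  n <- nrow(a)
  if (k_max >= n) stop("k_max must be smaller than the number of cells")
  la <- knn_lists(a, k_max, metric)
  lb <- knn_lists(b, k_max, metric)
  # rank of each neighbor in the other embedding's list (Inf if absent)
  ks <- k_min:k_max
  overlap <- numeric(length(ks))
  rank_b <- matrix(Inf, n, k_max)
  for (i in seq_len(n)) {
    pos <- match(la[i, ], lb[i, ])
    rank_b[i, ] <- ifelse(is.na(pos), Inf, pos)
  }
  for (t in seq_along(ks)) {
    k <- ks[t]
    overlap[t] <- sum(rank_b[, seq_len(k)] <= k) / (n * k)
  }
  mean(overlap)
}

#' Shuffle the nonzero values of a count matrix
#'
#' Permutes the multiset of nonzero counts uniformly among the nonzero
#' positions, leaving the zero pattern untouched. This destroys the
#' magnitude ("non-binary") information while preserving the binary
#' expressed/not-expressed structure.
#'
#' @param cm a [count_matrix()].
#' @param seed integer RNG seed.
#' @return A `count_matrix` with permuted nonzero values.
#' @export
shuffle_nonzeros <- function(cm, seed) {
  stopifnot(inherits(cm, "count_matrix"))
  v <- cm$values
  with_seed(seed, {
    v@x <- sample(v@x)
  })
  count_matrix(v, cm$cell_ids, cm$gene_names,
               meta = c(cm$meta, list(shuffled = list(seed = seed))))
}

#' Silhouette drop after shuffling nonzero counts
#'
#' Runs the full reduction pipeline on the data and on a nonzero-shuffled
#' copy, embeds both in 2-D with UMAP, and returns the difference of the
#' ground-truth silhouette scores, `SIL - SIL_shuffled`. A value near 0
#' means the cluster structure lives in the zero pattern; a large positive
#' value means it lives in the count magnitudes.
#'
#' @param cm a [count_matrix()].
#' @param labels ground-truth labels, one per cell.
#' @param seed integer master seed (drives the shuffle, the pipeline and
#'   UMAP).
#' @param config pipeline configuration from [sc_config()].
#' @return `SIL - SIL_shuffled`, with both scores in attribute
#'   `"components"`.
#' @export
delta_sil <- function(cm, labels, seed = 1, config = sc_config(seed = seed)) {
  stopifnot(inherits(cm, "count_matrix"))
  seeds <- spawn_seeds(seed, 3)
  emb <- run_pipeline(cm, config)$embedding
  config_s <- config
  config_s$seed <- seeds[2]
  emb_s <- run_pipeline(shuffle_nonzeros(cm, seeds[1]), config_s)$embedding
  e2 <- embed_2d(emb, seed = seeds[3])
  e2s <- embed_2d(emb_s, seed = seeds[3])
  sil <- silhouette_score(e2, labels)
  sil_s <- silhouette_score(e2s, labels)
  out <- sil - sil_s
  attr(out, "components") <- c(SIL = sil, SIL_shuffled = sil_s)
  out
}

#' 2-D UMAP embedding of a reduced representation
#'
#' Thin wrapper around `uwot::umap` with the settings used throughout:
#' 15 nearest neighbors, minimum distance 0.01, cosine metric.
#'
#' @param emb an `sc_embedding` or score matrix.
#' @param seed integer RNG seed.
#' @param n_neighbors,min_dist,metric UMAP parameters.
#' @return n x 2 coordinate matrix.
#' @export
embed_2d <- function(emb, seed = 1, n_neighbors = 15, min_dist = 0.01,
                     metric = "cosine") {
  if (!requireNamespace("uwot", quietly = TRUE)) {
    stop("embed_2d requires the uwot package")
  }
  x <- scores_of(emb)
  init <- "spectral"
  if (ncol(x) == 1) {
    # a single signal dimension: cosine reduces to sign, so fall back to
    # euclidean distances and a random (seeded) layout initialization
    x <- cbind(x, 0)
    metric <- "euclidean"
    init <- "random"
  }
  with_seed(seed, {
    uwot::umap(x, n_neighbors = min(n_neighbors, nrow(x) - 1),
               min_dist = min_dist, metric = metric, init = init,
               n_threads = 1, n_sgd_threads = 1)
  })
}

#' Depth-downsample a count matrix
#'
#' Subsamples transcripts within each cell without replacement (weighted
#' by the cell's own counts) so that the matrix-wide mean total gene
#' count is approximately `target_mean_tgc`. Entries never exceed their
#' original values and the zero pattern can only gain zeros.
#'
#' @param cm a [count_matrix()].
#' @param target_mean_tgc desired mean TGC; must not exceed the current
#'   mean.
#' @param seed integer RNG seed.
#' @return A downsampled `count_matrix`.
#' @export
downsample_counts <- function(cm, target_mean_tgc, seed) {
  stopifnot(inherits(cm, "count_matrix"), target_mean_tgc > 0)
  tgc <- total_counts(cm)
  cur <- mean(tgc)
  if (target_mean_tgc > cur) {
    stop(sprintf("target mean TGC (%.1f) exceeds current mean (%.1f)",
                 target_mean_tgc, cur))
  }
  if (target_mean_tgc == cur) return(cm)
  ratio <- target_mean_tgc / cur
  tr <- methods::as(cm$values, "TsparseMatrix")
  with_seed(seed, {
    new_x <- tr@x
    groups <- split(seq_along(tr@i), tr@i)
    for (sel in groups) {
      counts <- tr@x[sel]
      keep_total <- round(ratio * sum(counts))
      new_x[sel] <- multivariate_hypergeometric(counts, keep_total)
    }
    tr@x <- new_x
  })
  count_matrix(Matrix::drop0(tr), cm$cell_ids, cm$gene_names,
               meta = c(cm$meta, list(downsampled = list(
                 target_mean_tgc = target_mean_tgc, seed = seed))))
}

# Draw a multivariate hypergeometric sample: `k` transcripts taken without
# replacement from bins with occupancies `counts`.
multivariate_hypergeometric <- function(counts, k) {
  total <- sum(counts)
  out <- numeric(length(counts))
  remaining <- k
  left <- total
  for (j in seq_along(counts)) {
    if (remaining <= 0) break
    left <- left - counts[j]
    out[j] <- stats::rhyper(1, m = counts[j], n = left, k = remaining)
    remaining <- remaining - out[j]
  }
  out
}
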