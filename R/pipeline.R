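#' Pipeline configuration
#'
#' Collects every tunable of the reduction pipeline in one serializable
#' list. A run with the same configuration and input is reproducible:
#' deterministic stages are bit-identical and stochastic stages are
#' driven by sub-seeds spawned from the single master `seed`.
#'
#' @param qc apply [qc_filter()] first (default `TRUE`; synthetic
#'   matrices without gene names are usually run with `qc = FALSE`).
#' @param min_genes_per_cell,min_cells_per_gene,max_mito_fraction QC
#'   thresholds (defaults 200, 15, 0.05).
#' @param L log-normalization scale factor (default 1).
#' @param center gene-scaling centering, `"mean"` or `"median"` (the
#'   median variant preserves sparsity and memory on large data).
#' @param l2 apply L2 cell normalization (default `TRUE`).
#' @param alpha Tracy-Widom tail probability for the signal threshold
#'   (default 0.05).
#' @param robustness apply the signal robustness test (default `TRUE`).
#' @param k_perturb number of perturbation replicates (default 10).
#' @param robust_threshold robustness cutoff (default 0.5).
#' @param sparsity perturbation sparsity; `NULL` (default) selects it
#'   with [select_perturbation_sparsity()].
#' @param sparsity_start,sparsity_step,sparsity_floor sparsity-selection
#'   grid (defaults 0.999, 0.001, 0.9).
#' @param seed integer master seed.
#' @return A list of class `sc_config`.
#' @export
sc_config <- function(qc = TRUE, min_genes_per_cell = 200,
                      min_cells_per_gene = 15, max_mito_fraction = 0.05,
                      L = 1, center = c("mean", "median"), l2 = TRUE,
                      alpha = 0.05, robustness = TRUE, k_perturb = 10,
                      robust_threshold = 0.5, sparsity = NULL,
                      sparsity_start = 0.999, sparsity_step = 0.001,
                      sparsity_floor = 0.9, seed = 1) {
  center <- match.arg(center)
  structure(list(
    qc = qc, min_genes_per_cell = min_genes_per_cell,
    min_cells_per_gene = min_cells_per_gene,
    max_mito_fraction = max_mito_fraction,
    L = L, center = center, l2 = l2, alpha = alpha,
    robustness = robustness, k_perturb = k_perturb,
    robust_threshold = robust_threshold, sparsity = sparsity,
    sparsity_start = sparsity_start, sparsity_step = sparsity_step,
    sparsity_floor = sparsity_floor, seed = seed
  ), class = "sc_config")
}

#' Run the full signal-detection pipeline
#'
#' Executes, in order: reading (when given a path), quality control,
#' normalization (log, gene scaling, L2), full eigendecomposition of the
#' cell-similarity matrix, Marchenko-Pastur fit, Tracy-Widom
#' thresholding, signal detection, the signal robustness test, robust
#' signal selection and embedding construction. Every stochastic stage
#' draws its seed from the master seed in `config`.
#'
#' @param x a [count_matrix()], or a path (with `fmt` given).
#' @param config an [sc_config()].
#' @param fmt input format when `x` is a path (see [read_counts()]).
#' @param output_dir optional directory; when given, the embedding (CSV),
#'   signal/robustness sidecars (JSON), resolved configuration (JSON) and
#'   a run log are written there.
#' @return List with elements `embedding` (robust-signal `sc_embedding`),
#'   `signals` (all TW-exceeding signals), `robust_signals`, `report`
#'   (`robustness_report` or `NULL`), `mp_fit`, `spectrum`, `config`,
#'   `log` (character vector).
#' @export
run_pipeline <- function(x, config = sc_config(), fmt = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "sc_config"))
  log <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    message(line)
  }
  cm <- if (inherits(x, "count_matrix")) x else read_counts(x, fmt)
  note("input: %d cells x %d genes", nrow(cm$values), ncol(cm$values))
  if (isTRUE(config$qc)) {
    cm <- qc_filter(cm, config$min_genes_per_cell, config$min_cells_per_gene,
                    config$max_mito_fraction)
    note("post-QC: %d cells x %d genes (removed: %d low-coverage, %d mito, %d genes)",
         nrow(cm$values), ncol(cm$values),
         cm$meta$qc$cells_removed_low_coverage, cm$meta$qc$cells_removed_mito,
         cm$meta$qc$genes_removed)
  }
  nm <- preprocess(cm, L = config$L, center = config$center, l2 = config$l2)
  spec <- full_spectrum(nm)
  note("spectrum: %d eigenpairs, top eigenvalue %.4g", length(spec$values),
       spec$values[1])
  fit <- fit_marchenko_pastur(spec)
  note("MP fit: sigma2 = %.4g, lambda_plus = %.4g, bulk = %d, KS = %.3f",
       fit$sigma2, fit$lambda_plus, fit$n_bulk,
       fit$fit_diagnostics$ks_distance)
  thr <- tracy_widom_threshold(fit, spec$n_cells, spec$n_genes, config$alpha)
  signals <- detect_signals(spec, thr, mp_fit = fit)
  note("TW threshold %.4g (alpha = %.3g): %d signal(s)", thr, config$alpha,
       n_signals(signals))
  if (n_signals(signals) == 0) {
    err <- simpleError("no eigenvalue exceeds the Tracy-Widom threshold; the data are indistinguishable from noise under this preprocessing")
    err$mp_fit <- fit
    err$spectrum_summary <- summary(spec$values)
    err$log <- log
    stop(err)
  }
  seeds <- spawn_seeds(config$seed, 2)
  report <- NULL
  robust <- signals
  if (isTRUE(config$robustness)) {
    sparsity <- config$sparsity
    if (is.null(sparsity)) {
      sparsity <- tryCatch(
        select_perturbation_sparsity(
          cm, start = config$sparsity_start, step = config$sparsity_step,
          floor = config$sparsity_floor, seed = seeds[1],
          L = config$L, center = config$center, l2 = config$l2),
        error = function(e) {
          # every tested level left the binarized structure intact, so the
          # stop condition never fired; fall back to a conservative level
          note("sparsity selection did not trigger (%s); using 0.97",
               conditionMessage(e))
          0.97
        })
      note("perturbation sparsity: %.4f", as.numeric(sparsity))
    }
    report <- signal_robustness(cm, signals, sparsity = as.numeric(sparsity),
                                K = config$k_perturb, seed = seeds[2],
                                L = config$L, center = config$center,
                                l2 = config$l2)
    robust <- select_robust(signals, report, config$robust_threshold)
    note("robustness test (K = %d): %d of %d signal(s) robust",
         config$k_perturb, n_signals(robust), n_signals(signals))
  }
  embedding <- NULL
  if (n_signals(robust) > 0) {
    embedding <- build_embedding(robust)
    embedding$source <- if (isTRUE(config$robustness)) "rmt+robust" else "rmt"
  } else {
    note("no robust signals; returning NULL embedding")
  }
  result <- list(embedding = embedding, signals = signals,
                 robust_signals = robust, report = report, mp_fit = fit,
                 spectrum = spec, config = config, log = log)
  if (!is.null(output_dir)) {
    write_run(result, output_dir)
  }
  result
}

# Serialize run artifacts: embedding CSV, JSON sidecars, resolved config,
# log file.
write_run <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$embedding)) {
    df <- data.frame(cell_id = result$embedding$cell_ids %||%
                       seq_len(nrow(result$embedding$scores)),
                     result$embedding$scores, check.names = FALSE)
    utils::write.csv(df, file.path(output_dir, "embedding.csv"),
                     row.names = FALSE)
  }
  fit <- result$mp_fit
  sidecar <- list(
    eigenvalues = result$spectrum$values,
    tw_threshold = result$signals$tw_threshold,
    signal_indices = result$signals$indices,
    robust_indices = result$robust_signals$indices,
    mp_fit = list(sigma2 = fit$sigma2, gamma = fit$gamma,
                  lambda_minus = fit$lambda_minus,
                  lambda_plus = fit$lambda_plus, n_bulk = fit$n_bulk,
                  diagnostics = fit$fit_diagnostics)
  )
  jsonlite::write_json(sidecar, file.path(output_dir, "signals.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$report)) {
    r <- result$report
    jsonlite::write_json(
      list(robustness = r$robustness,
           per_replicate = r$per_replicate,
           perturbation_sparsity = r$perturbation_sparsity,
           K = r$K, seeds = r$seeds),
      file.path(output_dir, "robustness.json"), auto_unbox = TRUE,
      digits = NA)
  }
  jsonlite::write_json(unclass(result$config),
                       file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(result$log, file.path(output_dir, "log.txt"))
  invisible(output_dir)
}

#' Cluster an embedding
#'
#' Clustering harness used for evaluation: hierarchical clustering (Ward
#' linkage on Euclidean distances) cut at `k` clusters, or Leiden
#' community detection on a shared-nearest-neighbor graph (20 neighbors,
#' edge cutoff 1/15, cosine metric) when `method = "leiden"`.
#'
#' @param emb an `sc_embedding` or score matrix.
#' @param k number of clusters (hierarchical) .
#' @param method `"hclust"` (default) or `"leiden"`.
#' @param resolution Leiden resolution parameter (default 1).
#' @param snn_neighbors,snn_cutoff SNN graph parameters (defaults 20 and
#'   1/15).
#' @param seed RNG seed for Leiden.
#' @return Integer cluster assignment, one per cell.
#' @export
cluster_embedding <- function(emb, k = NULL, method = c("hclust", "leiden"),
                              resolution = 1, snn_neighbors = 20,
                              snn_cutoff = 1 / 15, seed = 1) {
  method <- match.arg(method)
  x <- scores_of(emb)
  if (method == "hclust") {
    if (is.null(k)) stop("k is required for hierarchical clustering")
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    return(stats::cutree(hc, k = k))
  }
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("leiden clustering requires the igraph package")
  }
  n <- nrow(x)
  kn <- min(snn_neighbors, n - 1)
  nb <- knn_lists(x, kn, metric = "cosine")
  # shared-neighbor fraction between each cell and its kNN
  edges <- list()
  w <- list()
  for (i in seq_len(n)) {
    for (j in nb[i, ]) {
      shared <- length(intersect(nb[i, ], nb[j, ])) / kn
      if (shared >= snn_cutoff && i < j) {
        edges[[length(edges) + 1]] <- c(i, j)
        w[[length(w) + 1]] <- shared
      }
    }
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = unlist(w))
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  with_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution)$membership
  })
}
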