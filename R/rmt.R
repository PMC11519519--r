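#' Cell-similarity (Gram) matrix
#'
#' Computes `G = X %*% t(X) / N` over the normalized cells x genes matrix
#' `X`, where `N` is the number of genes. Diagonals are squared
#' cell-vector lengths (all equal to `1/N` after L2 normalization);
#' off-diagonals measure directional similarity between cells.
#'
#' @param nm a `normalized_matrix` (or a plain numeric matrix).
#' @return Dense symmetric M x M matrix.
#' @export
gram_matrix <- function(nm) {
  x <- if (inherits(nm, "normalized_matrix")) nm$values else nm
  g <- as.matrix(Matrix::tcrossprod(x)) / ncol(x)
  (g + t(g)) / 2
}

#' Full eigendecomposition of the cell-similarity matrix
#'
#' Returns all `min(M, N)` eigenpairs of `G = XX'/N`, sorted by decreasing
#' eigenvalue. The decomposition is carried out on whichever side of the
#' Gram matrix is smaller: when `N < M` the gene-side `X'X/N` is
#' decomposed and cell-side eigenvectors recovered as `X v / sqrt(N l)`,
#' which yields identical eigenvalues and (up to sign) eigenvectors.
#'
#' @param x a `normalized_matrix` or a plain numeric cells x genes data
#'   matrix; with `is_gram = TRUE`, a precomputed symmetric Gram matrix
#'   (whose aspect ratio information is then lost: `n_genes` is set to its
#'   dimension).
#' @param is_gram interpret a plain matrix as a precomputed Gram matrix
#'   (default `FALSE`).
#' @return An object of class `gram_spectrum` with fields `values`
#'   (descending), `vectors` (cells x n_pairs, orthonormal columns),
#'   `n_cells`, `n_genes`.
#' @export
full_spectrum <- function(x, is_gram = FALSE) {
  if (!inherits(x, "normalized_matrix") && !is_gram) {
    x <- normalized_matrix(x, rownames(x), colnames(x),
                           steps = list(list(step = "external")))
  }
  if (inherits(x, "normalized_matrix")) {
    xm <- x$values
    m <- nrow(xm); n <- ncol(xm)
    if (!all(is.finite(if (methods::is(xm, "Matrix")) xm@x else xm))) {
      stop("non-finite entries in normalized matrix")
    }
    if (m <= n) {
      g <- gram_matrix(x)
      e <- eigen(g, symmetric = TRUE)
      vals <- e$values
      vecs <- e$vectors
    } else {
      gg <- as.matrix(Matrix::crossprod(xm)) / n
      e <- eigen((gg + t(gg)) / 2, symmetric = TRUE)
      vals <- e$values
      u <- as.matrix(xm %*% e$vectors)
      scal <- sqrt(pmax(n * vals, .Machine$double.eps))
      vecs <- sweep(u, 2, scal, "/")
      # re-orthonormalize columns whose eigenvalue is numerically zero
      nrm <- sqrt(colSums(vecs^2))
      ok <- nrm > 0.5
      vecs[, ok] <- sweep(vecs[, ok, drop = FALSE], 2, nrm[ok], "/")
    }
    k <- min(m, n)
    spec <- list(values = vals[seq_len(k)],
                 vectors = vecs[, seq_len(k), drop = FALSE],
                 n_cells = m, n_genes = n,
                 cell_ids = if (!is.null(x$cell_ids)) x$cell_ids else NULL)
  } else {
    g <- as.matrix(x)
    if (!all(is.finite(g))) stop("non-finite entries in Gram matrix")
    e <- eigen((g + t(g)) / 2, symmetric = TRUE)
    spec <- list(values = e$values, vectors = e$vectors,
                 n_cells = nrow(g), n_genes = nrow(g), cell_ids = rownames(g))
  }
  class(spec) <- "gram_spectrum"
  spec
}

# Marchenko-Pastur density for eigenvalues of XX'/N (X: M x N, entry
# variance sigma2, gamma = M/N <= 1 assumed on the cell side; the formula
# is used with gamma = M/N regardless, matching the Gram normalization).
mp_density <- function(lambda, sigma2, gamma) {
  lp <- sigma2 * (1 + sqrt(gamma))^2
  lm <- sigma2 * (1 - sqrt(gamma))^2
  d <- numeric(length(lambda))
  inside <- lambda > lm & lambda < lp
  li <- lambda[inside]
  d[inside] <- sqrt((lp - li) * (li - lm)) / (2 * pi * sigma2 * gamma * li)
  d
}

# Integrals of the MP density under the substitution
# lambda = lm + (lp - lm) sin^2(theta), which removes the inverse-
# square-root edge singularities (including the one at lambda -> 0 when
# gamma = 1). Returns theta grid, lambda grid and the transformed
# integrand so callers can form mass/moment/CDF integrals.
mp_theta_quad <- function(sigma2, gamma, n_grid = 2048) {
  lp <- sigma2 * (1 + sqrt(gamma))^2
  lm <- sigma2 * (1 - sqrt(gamma))^2
  theta <- seq(0, pi / 2, length.out = n_grid)
  lam <- lm + (lp - lm) * sin(theta)^2
  # p(lambda) dlambda = (lp-lm)^2 2 sin^2 cos^2 / (2 pi sigma2 gamma lam) dtheta
  f <- (lp - lm)^2 * 2 * (sin(theta) * cos(theta))^2 /
    (2 * pi * sigma2 * gamma * pmax(lam, .Machine$double.xmin))
  if (lm == 0) f[1] <- lp / (pi * sigma2 * gamma) # limit at theta = 0
  list(theta = theta, lambda = lam, f = f, lm = lm, lp = lp)
}

mp_cdf <- function(lambda, sigma2, gamma, n_grid = 2048) {
  q <- mp_theta_quad(sigma2, gamma, n_grid)
  dt <- diff(q$theta)
  cum <- c(0, cumsum((q$f[-1] + q$f[-n_grid]) / 2 * dt))
  cdf <- cum / max(cum[n_grid], .Machine$double.eps)
  stats::approx(q$lambda, cdf, xout = pmin(pmax(lambda, q$lm), q$lp),
                rule = 2, ties = "ordered")$y
}

# Mean of the MP law (normalized over its support) truncated at `cutoff`,
# as a function of sigma2. The renormalization over the support makes the
# same expression valid for gamma above 1, where only the nonzero
# eigenvalues are observed.
mp_truncated_mean <- function(sigma2, gamma, cutoff = Inf, n_grid = 2048) {
  q <- mp_theta_quad(sigma2, gamma, n_grid)
  if (min(cutoff, q$lp) <= q$lm) return(NA_real_)
  keep <- q$lambda <= cutoff
  if (sum(keep) < 2) return(NA_real_)
  th <- q$theta[keep]; f <- q$f[keep]; lam <- q$lambda[keep]
  dt <- diff(th)
  mass <- sum((f[-1] + f[-length(f)]) / 2 * dt)
  if (mass <= 0) return(NA_real_)
  mom <- sum((lam[-1] * f[-1] + lam[-length(f)] * f[-length(f)]) / 2 * dt)
  mom / mass
}

#' Fit the Marchenko-Pastur distribution to a Gram spectrum
#'
#' Estimates the noise variance scale `sigma2` at fixed aspect ratio
#' `gamma = M/N` by matching the mean of the bulk eigenvalues to the
#' (truncation-corrected) MP mean, with iterative trimming: all
#' eigenvalues are used initially, eigenvalues above the fitted upper
#' edge are dropped, and the fit is repeated to a fixed point. Spiked
#' (signal) eigenvalues are thereby excluded from the bulk without any
#' manual choice, and the moment equation accounts for the bulk mass the
#' trimming cuts off.
#'
#' @param spec a `gram_spectrum` (needs at least 30 eigenvalues).
#' @param max_iter maximum trimming iterations (default 100).
#' @param tol relative convergence tolerance on `sigma2` (default 1e-6).
#' @param trim_quantile Tracy-Widom quantile defining the trimming
#'   cutoff above the fitted edge (default 0.999): eigenvalues beyond
#'   `lambda_plus` by more than this fluctuation margin are treated as
#'   outliers, so ordinary edge fluctuations of a pure-noise spectrum are
#'   retained in the bulk while genuine spikes are excluded.
#' @return An object of class `mp_fit` with fields `sigma2`, `gamma`,
#'   `lambda_minus`, `lambda_plus`, `n_bulk`, and `fit_diagnostics`
#'   (iterations, Kolmogorov-Smirnov distance of the bulk to the fitted
#'   MP law, convergence flag).
#' @export
fit_marchenko_pastur <- function(spec, max_iter = 100, tol = 1e-6,
                                 trim_quantile = 0.999) {
  stopifnot(inherits(spec, "gram_spectrum"))
  lambdas <- pmax(spec$values, 0)
  if (length(lambdas) < 30) {
    stop("MP fit needs at least 30 eigenvalues; got ", length(lambdas))
  }
  gamma <- spec$n_cells / spec$n_genes
  sm <- sqrt(spec$n_cells - 0.5)
  sn <- sqrt(spec$n_genes - 0.5)
  tw_scale_unit <- ((sm + sn) / spec$n_genes) * (1 / sm + 1 / sn)^(1 / 3)
  trim_margin <- tw_scale_unit * qtw1(trim_quantile) # per unit sigma2
  solve_sigma2 <- function(bulk, cutoff) {
    target <- mean(bulk)
    f <- function(s2) {
      tm <- mp_truncated_mean(s2, gamma, cutoff)
      if (is.na(tm)) tm <- cutoff # support collapsed above the cutoff
      tm - target
    }
    lo <- target / (10 * max(gamma, 1))
    hi <- target * 10
    while (f(hi) < 0 && hi < target * 1e4) hi <- hi * 2
    stats::uniroot(f, interval = c(lo, hi), tol = 1e-10)$root
  }
  bulk <- lambdas
  cutoff <- Inf
  sigma2 <- mean(bulk)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    new_sigma2 <- solve_sigma2(bulk, cutoff)
    lp <- new_sigma2 * (1 + sqrt(gamma))^2
    new_cutoff <- lp + new_sigma2 * trim_margin
    new_bulk <- lambdas[lambdas <= new_cutoff]
    done <- abs(new_sigma2 - sigma2) < tol * max(sigma2, 1e-12) &&
      length(new_bulk) == length(bulk)
    sigma2 <- new_sigma2
    bulk <- new_bulk
    cutoff <- new_cutoff
    if (done) { converged <- TRUE; break }
    if (length(bulk) < 30) {
      stop("MP fit trimmed away too many eigenvalues (", length(bulk),
           " left); spectrum may not contain an MP bulk")
    }
  }
  lp <- sigma2 * (1 + sqrt(gamma))^2
  lm <- sigma2 * (1 - sqrt(gamma))^2
  ecdf_vals <- stats::ecdf(bulk)(sort(bulk))
  ks <- max(abs(ecdf_vals - mp_cdf(sort(bulk), sigma2, gamma)))
  fit <- list(sigma2 = sigma2, gamma = gamma, lambda_minus = lm,
              lambda_plus = lp, n_bulk = length(bulk),
              fit_diagnostics = list(iterations = iter, ks_distance = ks,
                                     converged = converged))
  class(fit) <- "mp_fit"
  if (!converged) {
    cond <- simpleError(sprintf(
      "MP fit did not converge in %d iterations (last sigma2 = %.6g)",
      max_iter, sigma2))
    cond$fit <- fit
    stop(cond)
  }
  fit
}

# Tracy-Widom (beta = 1) quantile via the shifted-Gamma approximation of
# Chiani (2014), accurate to ~1e-4 over the practical quantile range.
tw1_gamma_params <- list(k = 46.44604884, theta = 0.18605402228, alpha = 9.84801210848)

#' Quantile of the Tracy-Widom distribution (beta = 1)
#'
#' @param p probability in (0,1).
#' @return The TW1 quantile, computed from a shifted-Gamma approximation
#'   whose first three moments match the TW1 law.
#' @export
qtw1 <- function(p) {
  stopifnot(all(p > 0 & p < 1))
  stats::qgamma(p, shape = tw1_gamma_params$k, scale = tw1_gamma_params$theta) -
    tw1_gamma_params$alpha
}

#' CDF of the Tracy-Widom distribution (beta = 1)
#' @param q quantile.
#' @return Probability `P(TW1 <= q)`.
#' @export
ptw1 <- function(q) {
  stats::pgamma(q + tw1_gamma_params$alpha, shape = tw1_gamma_params$k,
                scale = tw1_gamma_params$theta)
}

#' Tracy-Widom signal threshold
#'
#' The critical eigenvalue beyond which a pure-noise eigenvalue has
#' probability `alpha` of being observed: the fitted MP upper edge plus
#' the Tracy-Widom fluctuation scale times the `1 - alpha` TW1 quantile.
#' The fluctuation scale uses the Johnstone sample-covariance convention
#' (with the 1/2 finite-size correction), rescaled by the fitted noise
#' variance.
#'
#' @param fit an `mp_fit`.
#' @param M,N number of cells and genes the spectrum came from.
#' @param alpha tail probability (default 0.05).
#' @return Numeric threshold on the eigenvalue scale of `G = XX'/N`.
#' @export
tracy_widom_threshold <- function(fit, M, N, alpha = 0.05) {
  stopifnot(inherits(fit, "mp_fit"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  sm <- sqrt(M - 0.5)
  sn <- sqrt(N - 0.5)
  scale_tw <- fit$sigma2 * ((sm + sn) / N) * (1 / sm + 1 / sn)^(1 / 3)
  fit$lambda_plus + scale_tw * qtw1(1 - alpha)
}

#' Extract signal eigenpairs above a threshold
#'
#' Eigenvalues strictly greater than the threshold and their eigenvectors
#' are retained as potential biological signals; everything at or below it
#' is treated as noise. An empty result is valid (pure-noise data).
#'
#' @param spec a `gram_spectrum`.
#' @param threshold numeric threshold, typically from
#'   [tracy_widom_threshold()].
#' @param mp_fit optional `mp_fit` recorded alongside.
#' @return An object of class `signal_set` with fields `indices`,
#'   `eigenvalues`, `vectors` (cells x n_signals), `tw_threshold`,
#'   `mp_fit`, `cell_ids`.
#' @export
detect_signals <- function(spec, threshold, mp_fit = NULL) {
  stopifnot(inherits(spec, "gram_spectrum"), is.finite(threshold))
  idx <- which(spec$values > threshold)
  out <- list(indices = idx,
              eigenvalues = spec$values[idx],
              vectors = spec$vectors[, idx, drop = FALSE],
              tw_threshold = threshold,
              mp_fit = mp_fit,
              cell_ids = spec$cell_ids)
  class(out) <- "signal_set"
  out
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("signal_set: %d signal(s) above threshold %.4g\n",
              length(x$eigenvalues), x$tw_threshold))
  invisible(x)
}

#' Number of signals in a signal set
#' @param signals a `signal_set`.
#' @return integer count.
#' @export
n_signals <- function(signals) length(signals$eigenvalues)

#' Build the reduced embedding from signal eigenpairs
#'
#' The score matrix `V_sig %*% diag(sqrt(lambda))`, which is equal (up to
#' per-column sign) to the PC score matrix that conventional PCA on the
#' same normalized matrix would give for those components.
#'
#' @param signals a non-empty `signal_set`.
#' @return An object of class `sc_embedding` with fields `scores` (cells x
#'   n_signals), `eigenvalues`, `source`, `cell_ids`.
#' @export
build_embedding <- function(signals) {
  stopifnot(inherits(signals, "signal_set"))
  if (n_signals(signals) == 0) {
    stop("no signals to embed; inspect the MP fit diagnostics and the ",
         "eigenvalue spectrum (the data may be indistinguishable from noise)")
  }
  scores <- sweep(signals$vectors, 2, sqrt(signals$eigenvalues), "*")
  colnames(scores) <- paste0("SC", seq_len(ncol(scores)))
  out <- list(scores = scores, eigenvalues = signals$eigenvalues,
              source = "rmt", cell_ids = signals$cell_ids)
  class(out) <- "sc_embedding"
  out
}

#' @export
print.sc_embedding <- function(x, ...) {
  cat(sprintf("sc_embedding (%s): %d cells x %d dimensions\n",
              x$source, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}
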