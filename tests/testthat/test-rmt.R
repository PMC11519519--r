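test_that("the Gram matrix matches its definition", {
  nm <- scsignal:::normalized_matrix(diag(3), paste0("c", 1:3),
                                     paste0("g", 1:3), steps = list())
  expect_equal(gram_matrix(nm), diag(3) / 3, ignore_attr = TRUE)
  # brute-force double loop on a random matrix
  x <- matrix(rnorm(20 * 40), 20)
  g <- gram_matrix(x)
  ref <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) ref[i, j] <- sum(x[i, ] * x[j, ]) / 40
  expect_lt(max(abs(g - ref)), 1e-10)
  expect_lt(max(abs(g - t(g))), 1e-12)
})

test_that("the full spectrum reconstructs its input and matches on both sides", {
  # diagonal case
  sp <- full_spectrum(diag(c(3, 2, 1)), is_gram = TRUE)
  expect_equal(sp$values, c(3, 2, 1))
  expect_equal(abs(sp$vectors), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  # reconstruction of a random PSD matrix
  withr::with_seed(4, {
    a <- matrix(rnorm(30 * 30), 30)
    g <- crossprod(a) / 30
  })
  sp2 <- full_spectrum(g, is_gram = TRUE)
  expect_lt(max(abs(sp2$vectors %*% diag(sp2$values) %*% t(sp2$vectors) - g)),
            1e-8)
  expect_lt(max(abs(crossprod(sp2$vectors) - diag(30))), 1e-8)
  # cell-side vs gene-side path agree up to column sign
  withr::with_seed(5, x <- matrix(rnorm(50 * 30), 50))
  tall <- full_spectrum(x)                 # 50 cells x 30 genes: gene side
  wide <- full_spectrum(gram_matrix(x), is_gram = TRUE) # direct cell side
  expect_equal(length(tall$values), 30L)
  expect_equal(tall$values, wide$values[1:30], tolerance = 1e-8)
  for (k in 1:30) {
    agree <- min(max(abs(tall$vectors[, k] - wide$vectors[, k])),
                 max(abs(tall$vectors[, k] + wide$vectors[, k])))
    expect_lt(agree, 1e-6)
  }
})

test_that("the MP fit recovers the noise scale and is spike-robust", {
  withr::with_seed(8, x <- matrix(rnorm(300 * 1200), 300))
  fit <- fit_marchenko_pastur(full_spectrum(x))
  expect_equal(fit$gamma, 0.25)
  expect_lt(abs(fit$sigma2 - 1), 0.05)
  expect_lt(abs(fit$lambda_plus - 2.25), 0.12)
  expect_equal(fit$lambda_plus, fit$sigma2 * (1 + sqrt(fit$gamma))^2,
               tolerance = 1e-9)
  # scale covariance
  fit2 <- fit_marchenko_pastur(full_spectrum(2 * x))
  expect_lt(abs(fit2$sigma2 - 4 * fit$sigma2), 0.02)
  # planted spikes far above the bulk leave sigma2 unchanged
  withr::with_seed(9, {
    spikes <- matrix(rnorm(300 * 5), 300)
    xs <- x + 3 * spikes %*% matrix(rnorm(5 * 1200, sd = 0.2), 5)
  })
  fit3 <- fit_marchenko_pastur(full_spectrum(xs))
  expect_lt(abs(fit3$sigma2 - fit$sigma2) / fit$sigma2, 0.05)
  expect_lt(fit3$n_bulk, 300)
  expect_error(fit_marchenko_pastur(full_spectrum(diag(5), is_gram = TRUE)),
               "at least 30")
})

test_that("Tracy-Widom quantiles and threshold behave as a tail law should", {
  # pinned against published TW1 percentiles
  expect_equal(qtw1(0.95), 0.9793, tolerance = 2e-3)
  expect_equal(qtw1(0.99), 2.0234, tolerance = 1e-2)
  expect_equal(ptw1(qtw1(0.5)), 0.5, tolerance = 1e-10)
  withr::with_seed(10, x <- matrix(rnorm(200 * 800), 200))
  fit <- fit_marchenko_pastur(full_spectrum(x))
  thr <- function(a) tracy_widom_threshold(fit, 200, 800, a)
  expect_gt(thr(0.05), fit$lambda_plus)
  expect_gt(thr(0.01), thr(0.05)) # monotone decreasing in alpha
  expect_gt(thr(0.05), thr(0.5))
  expect_error(thr(0), "alpha")
  # threshold scales linearly with sigma2
  fit2 <- fit
  fit2$sigma2 <- 2 * fit$sigma2
  fit2$lambda_plus <- 2 * fit$lambda_plus
  expect_equal(tracy_widom_threshold(fit2, 200, 800, 0.05), 2 * thr(0.05),
               tolerance = 1e-12)
})

test_that("signal detection is a strict threshold rule", {
  sp <- full_spectrum(diag(c(5, 3, 1, 0.5, 0.1)), is_gram = TRUE)
  s <- detect_signals(sp, 3) # eigenvalue == threshold counts as noise
  expect_equal(s$eigenvalues, 5)
  expect_equal(s$indices, 1L)
  empty <- detect_signals(sp, 10)
  expect_equal(n_signals(empty), 0L)
  expect_error(build_embedding(empty), "no signal")
})

test_that("the embedding equals PC scores up to column sign", {
  withr::with_seed(12, x <- matrix(rnorm(100 * 60), 100))
  x <- scale(x, scale = FALSE)
  sp <- full_spectrum(x)
  emb <- build_embedding(detect_signals(sp, 0.05))
  expect_gt(ncol(emb$scores), 3)
  pca <- stats::prcomp(x, center = FALSE) # independent PCA implementation
  # G = XX'/N scales eigenvalues by 1/N, so PC scores carry a sqrt(N) factor
  pcs <- pca$x / sqrt(ncol(x))
  for (j in seq_len(ncol(emb$scores))) {
    dev <- min(max(abs(emb$scores[, j] - pcs[, j])),
               max(abs(emb$scores[, j] + pcs[, j])))
    expect_lt(dev, 1e-6)
  }
  # column norms are sqrt(eigenvalue) by construction
  expect_equal(sqrt(colSums(emb$scores^2)), sqrt(emb$eigenvalues),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("downstream results are invariant to eigenvector sign flips", {
  withr::with_seed(13, x <- matrix(rnorm(80 * 40), 80))
  sp <- full_spectrum(x)
  flipped <- sp
  flipped$vectors <- sweep(sp$vectors, 2, rep(c(1, -1), length.out = 40), "*")
  a <- build_embedding(detect_signals(sp, 0.5))
  b <- build_embedding(detect_signals(flipped, 0.5))
  expect_equal(abs(a$scores), abs(b$scores), tolerance = 1e-12)
  expect_equal(avg_knn_overlap(a$scores, b$scores, k_min = 5, k_max = 15,
                               metric = "euclidean"), 1)
})
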