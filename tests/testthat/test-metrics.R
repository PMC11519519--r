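test_that("silhouette matches the hand-computed two-cluster case", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  labs <- c("A", "A", "B", "B")
  s0 <- (10.5 - 1) / 10.5 # the point at 0
  s1 <- (9.5 - 1) / 9.5   # the point at 1
  expect_equal(silhouette_score(pts, labs), mean(c(s0, s1, s1, s0)),
               tolerance = 1e-12)
  # interleaved identical point sets overlap completely
  pts2 <- matrix(rep(c(0, 1, 2, 3), 2), ncol = 1)
  labs2 <- rep(c("A", "B"), each = 4)
  expect_lte(silhouette_score(pts2, labs2), 0)
  expect_error(silhouette_score(pts, rep("A", 4)), "single cluster")
})

test_that("silhouette agrees with the cluster package on random data", {
  skip_if_not_installed("cluster")
  withr::with_seed(7, {
    pts <- matrix(rnorm(60 * 3), 60)
    labs <- sample(1:4, 60, replace = TRUE)
  })
  ref <- mean(cluster::silhouette(labs, dist(pts))[, "sil_width"])
  expect_equal(silhouette_score(pts, labs), ref, tolerance = 1e-9)
})

test_that("singleton clusters contribute zero silhouette", {
  pts <- matrix(c(0, 1, 10, 20), ncol = 1)
  labs <- c("A", "A", "B", "C")
  # points 3 and 4 are singletons: s = 0 by convention; b is the nearest
  # other cluster's mean distance
  s_a0 <- (10 - 1) / 10
  s_a1 <- (9 - 1) / 9
  expect_equal(silhouette_score(pts, labs), mean(c(s_a0, s_a1, 0, 0)),
               tolerance = 1e-12)
})

test_that("element-centric similarity matches its hand and power-iteration oracles", {
  expect_equal(ecs(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # two elements: joint cluster vs singletons, d = 0.9
  expect_equal(ecs(c(1, 1), c(1, 2), d = 0.9), 0.5, tolerance = 1e-12)
  withr::with_seed(8, {
    for (rep in 1:3) {
      a <- sample(1:4, 30, replace = TRUE)
      b <- sample(1:3, 30, replace = TRUE)
      expect_equal(ecs(a, b), ecs_power_oracle(a, b), tolerance = 1e-6)
      expect_equal(ecs(a, b), ecs(b, a), tolerance = 1e-12) # symmetry
      expect_gte(ecs(a, b), 0)
      expect_lte(ecs(a, b), 1)
    }
  })
  expect_error(ecs(1:3, 1:4), "same length")
})

test_that("kNN overlap is exactly 1 for identical embeddings and near chance for scrambled ones", {
  withr::with_seed(9, emb <- matrix(rnorm(200 * 4), 200))
  expect_identical(avg_knn_overlap(emb, emb), 1)
  # well-separated clusters, then rows scrambled: neighborhoods destroyed
  withr::with_seed(10, {
    centers <- matrix(rnorm(8 * 4, sd = 8), 8)
    emb2 <- centers[rep(1:8, each = 25), ] + matrix(rnorm(200 * 4, sd = 0.2), 200)
    scram <- emb2[sample(200), ]
  })
  sc <- avg_knn_overlap(emb2, scram)
  expectation <- mean(5:50 / 199) # random-graph expected shared fraction
  expect_lt(sc, 2.5 * expectation)
  expect_lt(sc, 0.5) # far below identity
  # invariance under orthogonal rotation
  withr::with_seed(11, q <- qr.Q(qr(matrix(rnorm(16), 4))))
  expect_equal(avg_knn_overlap(emb, emb %*% q), 1, tolerance = 1e-12)
  expect_error(avg_knn_overlap(emb[1:20, ], emb[1:20, ]), "k_max")
})

test_that("nonzero shuffling permutes values on a fixed zero pattern", {
  cm <- random_counts(30, 40, density = 0.3, seed = 12)
  sh <- shuffle_nonzeros(cm, seed = 5)
  expect_equal(as.matrix(sh$values) > 0, as.matrix(cm$values) > 0)
  expect_equal(sort(sh$values@x), sort(cm$values@x))
  # equal nonzero values: shuffling is invisible
  ones <- binarize(cm)
  expect_equal(as.matrix(shuffle_nonzeros(ones, 5)$values),
               as.matrix(ones$values))
  sh2 <- shuffle_nonzeros(cm, seed = 6)
  expect_false(identical(as.matrix(sh$values), as.matrix(sh2$values)))
})

test_that("downsampling hits the target depth without creating counts", {
  cm <- poisson_block(m = 100, n = 300, lam = 25000 / 300, seed = 13)
  expect_gt(mean(total_counts(cm)), 20000)
  down <- downsample_counts(cm, 5000, seed = 14)
  expect_lt(abs(mean(total_counts(down)) - 5000) / 5000, 0.02)
  expect_true(all(as.matrix(down$values) <= as.matrix(cm$values)))
  # no-op when the target equals the current mean
  expect_identical(downsample_counts(cm, mean(total_counts(cm)), 1), cm)
  expect_error(downsample_counts(cm, 1e9, 1), "exceeds")
})

test_that("downsampled entries are unbiased at the depth ratio", {
  cm <- count_matrix(rbind(c(40, 20, 0, 10), c(8, 30, 12, 0)))
  ratio <- 0.4
  target <- ratio * mean(total_counts(cm))
  acc <- matrix(0, 2, 4)
  for (s in 1:200) {
    acc <- acc + as.matrix(downsample_counts(cm, target, seed = s)$values)
  }
  expect_lt(max(abs(acc / 200 - ratio * as.matrix(cm$values))), 1.5)
})

test_that("shuffling nonzeros leaves zero-pattern-encoded clusters intact", {
  skip_if_not_installed("uwot")
  # two clusters on disjoint gene supports with all nonzero values equal:
  # the shuffle permutes identical values, so the pipeline sees the same
  # data and the silhouette cannot change
  m <- matrix(0, 120, 240)
  m[1:60, 1:120] <- 1
  m[61:120, 121:240] <- 1
  withr::with_seed(15, noise <- matrix(rbinom(120 * 240, 1, 0.1), 120, 240))
  cm <- count_matrix(pmin(m + noise, 1))
  labs <- rep(c("a", "b"), each = 60)
  cfg <- sc_config(qc = FALSE, sparsity = 0.99, seed = 17)
  ds <- suppressWarnings(suppressMessages(delta_sil(cm, labs, seed = 17,
                                                    config = cfg)))
  comp <- attr(ds, "components")
  expect_gt(comp[["SIL"]], 0.5) # clusters are real
  expect_lt(abs(ds), 1e-8)      # and purely zero-pattern encoded
})
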