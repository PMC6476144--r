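test_that("PCA screen matches an independent SVD oracle", {
  set.seed(10)
  # random rank-5 curve matrix plus a touch of noise
  m <- matrix(rnorm(60 * 5), 60, 5) %*% matrix(rnorm(5 * 30), 5, 30) +
    matrix(rnorm(60 * 30, sd = 1e-3), 60, 30)
  ps <- pca_screen(m)
  sv <- svd(scale(m, center = TRUE, scale = FALSE))$d
  oracle_pct <- 100 * sv^2 / sum(sv^2)
  expect_equal(ps$explained_pct, oracle_pct, tolerance = 1e-8)
  expect_equal(sum(ps$explained_pct), 100, tolerance = 1e-6)
  expect_true(all(diff(ps$cumulative_pct) >= -1e-12))
})

test_that("curves in a 2D affine subspace are fully explained by 2 components", {
  set.seed(11)
  b1 <- sin(seq(0, 3, length.out = 25)); b2 <- seq(0, 1, length.out = 25)
  m <- outer(rnorm(40), b1) + outer(runif(40), b2) +
    matrix(rep(5 * b2, each = 40), 40)
  ps <- pca_screen(m)
  expect_equal(ps$cumulative_pct[2], 100, tolerance = 1e-8)
  expect_equal(n_components_for(ps, 90), 1L + (ps$explained_pct[1] < 90))
})

test_that("degenerate curve sets are rejected by the PCA screen", {
  m <- matrix(3, 10, 8)
  expect_error(pca_screen(m), "zero variance")
  expect_error(pca_screen(m[1, , drop = FALSE]), "at least 2")
})

test_that("k-means recovers duplicated prototypes exactly", {
  proto <- rbind(sin(seq(0, 3, length.out = 20)),
                 2 * cos(seq(0, 3, length.out = 20)))
  m <- proto[c(1, 2, 1, 1, 2, 2, 1, 2, 2, 1), ]
  res <- kmeans_segment(m, k = 2, seed = 1, assign_roles = FALSE)
  expect_equal(ari(res$labels, c(1, 2, 1, 1, 2, 2, 1, 2, 2, 1)), 1)
  expect_equal(res$inertia, 0, tolerance = 1e-20)
})

test_that("k-means inertia equals the exhaustive-partition optimum (n <= 8)", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    m <- matrix(rnorm(n * 12), n, 12)
    res <- kmeans_segment(m, k = 2, seed = rep, assign_roles = FALSE)
    expect_equal(res$inertia, brute_force_2means(m), tolerance = 1e-8)
  }
})

test_that("k-means segmentation is deterministic given the seed", {
  ph <- default_phantom(seed = 7)
  nde <- nde_of(ph)
  r1 <- kmeans_segment(nde, seed = 3)
  r2 <- kmeans_segment(nde, seed = 3)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$inertia, r2$inertia)
  expect_error(kmeans_segment(nde$curves[1:3, ], k = 5), "between 1")
})

test_that("noiseless phantom segmentation equals the true compartments", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0))
  res <- kmeans_segment(nde_of(ph), seed = 0)
  expect_identical(res$labels, truth_roles(ph$truth))
  expect_equal(ari(res$labels, truth_roles(ph$truth)), 1)
  # volume percentages mirror the mask pixel counts
  expect_equal(unname(res$volume_pct["inner"]),
               100 * sum(ph$truth$inner_mask) / sum(ph$truth$node_mask))
})

test_that("cluster roles follow enhancement magnitude, not input order", {
  lo <- c(rep(0, 3), seq(0.1, 1, length.out = 37))
  hi <- 2.17 * lo  # AUC ratio mirrors a strongly enhancing inner cluster
  m <- rbind(hi, hi, lo, lo, lo, lo)
  res <- kmeans_segment(m, k = 2, seed = 0)
  expect_identical(res$labels, c("inner", "inner", rep("outer", 4)))
  expect_equal(unname(res$volume_pct["inner"]), 100 * 2 / 6)
  # swapping the row order leaves role assignment unchanged
  res2 <- kmeans_segment(m[c(3:6, 1:2), ], k = 2, seed = 0)
  expect_identical(res2$labels, c(rep("outer", 4), "inner", "inner"))
  expect_equal(res$cluster_curves, res2$cluster_curves)
})

test_that("equal-AUC clusters are tie-broken by peak value", {
  # same area, different peaks: triangle vs plateau
  tall <- c(0, 0, 0, 4, 0, 0, 0, 0)
  flat <- c(0, 0, 1, 1, 1, 1, 0, 0)
  stopifnot(abs(auc(tall, 1, 1) - auc(flat, 1, 1)) < 1e-12)
  m <- rbind(tall, tall, flat, flat)
  res <- kmeans_segment(m, k = 2, seed = 0)
  expect_equal(res$tie_break, "peak")
  expect_identical(res$labels, c("inner", "inner", "outer", "outer"))
})

test_that("segmentation label map places roles at the node coordinates", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0))
  res <- kmeans_segment(nde_of(ph), seed = 0)
  expect_identical(res$label_map[ph$truth$inner_mask],
                   rep("inner", sum(ph$truth$inner_mask)))
  expect_true(all(is.na(res$label_map[!ph$truth$node_mask])))
})
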