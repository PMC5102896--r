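# k-means with restarts, silhouette analysis, depth ordering and the
# mode-filter label upsampling.

test_that("well-separated blobs are recovered exactly", {
  set.seed(10)
  n <- 150
  x <- rbind(matrix(rnorm(n * 3, 0, 1), ncol = 3),
             matrix(rnorm(n * 3, 50, 1), ncol = 3))
  truth <- rep(1:2, each = n)
  res <- kmeans_best_of(x, 2, n_restarts = 10, seed = 1)
  # brute-force nearest-mean check
  m1 <- colMeans(x[res$labels == 1, ])
  m2 <- colMeans(x[res$labels == 2, ])
  nearest <- apply(x, 1, function(p)
    which.min(c(sum((p - m1)^2), sum((p - m2)^2))))
  expect_equal(res$labels, as.integer(nearest))
  expect_equal(max(table(truth, res$labels)), n) # zero confusions
})

test_that("k equal to the number of distinct points gives objective 0", {
  x <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 3, 5), ncol = 2, byrow = TRUE)
  res <- kmeans_best_of(x, nrow(x), n_restarts = 5, seed = 2,
                        standardize = FALSE)
  expect_equal(res$objective, 0)
})

test_that("identical seed gives bit-identical labels and best objective kept", {
  fx <- tiny_features()
  r1 <- kmeans_best_of(fx$feats, 3, n_restarts = 15, seed = 42)
  r2 <- kmeans_best_of(fx$feats, 3, n_restarts = 15, seed = 42)
  expect_identical(r1$labels, r2$labels)
  expect_true(all(r1$objective <= r1$objectives))
  expect_length(r1$objectives, 15)
  expect_error(kmeans_best_of(fx$feats * NA, 2), "finite")
})

test_that("standardisation makes clustering invariant to affine rescaling", {
  fx <- tiny_features()
  x <- fx$feats[1:400, ]
  y <- sweep(sweep(x, 2, runif(ncol(x), 0.5, 20), "*"), 2,
             runif(ncol(x), -5, 5), "+")
  r1 <- kmeans_best_of(x, 3, n_restarts = 10, seed = 3)
  r2 <- kmeans_best_of(y, 3, n_restarts = 10, seed = 3)
  expect_identical(r1$labels, r2$labels)
})

test_that("silhouette matches the worked example and its bounds", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  s <- silhouette_values(x, c(1, 1, 2, 2))
  # direct formula evaluation: a(0) = 1, b(0) = (10 + 11)/2
  expect_equal(s[1], (10.5 - 1) / 10.5, tolerance = 1e-12)
  # all identical points: degenerate policy gives 0
  expect_equal(silhouette_values(matrix(1, 6, 2), rep(1:2, 3)), rep(0, 6))
  # any input: s in [-1, 1]
  set.seed(11)
  xr <- matrix(rnorm(300), ncol = 3)
  sr <- silhouette_values(xr, sample(1:4, 100, TRUE))
  expect_true(all(sr >= -1 & sr <= 1))
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(12)
  x <- matrix(rnorm(240), ncol = 3)
  labs <- kmeans_best_of(x, 3, n_restarts = 5, seed = 4,
                         standardize = FALSE)$labels
  ours <- silhouette_values(x, labs)
  ref <- cluster::silhouette(labs, stats::dist(x))[, "sil_width"]
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("silhouette curve reports local maxima over k", {
  set.seed(13)
  # three clear blobs: the curve over k = 2..5 peaks at 3
  x <- rbind(matrix(rnorm(200, 0, .5), ncol = 2),
             matrix(rnorm(200, 6, .5), ncol = 2),
             cbind(rnorm(100, 0, .5), rnorm(100, 6, .5)))
  sc <- silhouette_curve(x, k_range = 2:5, n_restarts = 5, seed = 5)
  expect_equal(nrow(sc$curve), 4)
  expect_true(3 %in% sc$candidates)
  expect_true(all(sc$curve$mean_silhouette >= -1 &
                    sc$curve$mean_silhouette <= 1))
})

test_that("depth ordering relabels without changing the partition", {
  fx <- tiny_features()
  res <- kmeans_best_of(fx$feats, 4, n_restarts = 10, seed = 6)
  ord <- order_clusters_by_depth(res, fx$samp$level)
  expect_equal(ord$objective, res$objective)
  # same partition, permuted ids
  expect_equal(length(unique(paste(res$labels, ord$labels))), 4)
  # cluster mean depths strictly increasing after relabel
  md <- tapply(fx$samp$level, ord$labels, mean)
  expect_true(all(diff(md) > 0))
  # two clusters at depths .2/.8 get ids 1/2
  toy <- kmeans_best_of(matrix(c(0, 0, 0, 10, 10, 10), ncol = 1), 2,
                        n_restarts = 3, seed = 7, standardize = FALSE)
  toy_ord <- order_clusters_by_depth(toy, c(0.8, 0.8, 0.8, 0.2, 0.2, 0.2))
  expect_equal(as.numeric(tapply(c(.8, .8, .8, .2, .2, .2), toy_ord$labels,
                                 mean)),
               c(0.2, 0.8))
})

test_that("mode-filter upsampling cleans isolated labels", {
  lab <- array(1L, c(6, 6, 6))
  up <- mode_filter_upsample(lab, factor = 3, window = 5)
  expect_equal(dim(up), c(18, 18, 18))
  expect_true(all(up == 1L)) # uniform volume unchanged
  # single discordant voxel inside a uniform region disappears
  lab2 <- array(1L, c(7, 7, 7))
  lab2[4, 4, 4] <- 2L
  up2 <- mode_filter_upsample(lab2, factor = 3, window = 5)
  expect_true(all(up2 == 1L))
  expect_error(mode_filter_upsample(array(1.5, c(3, 3, 3))), "integers")
})

test_that("sampled labels paint into a volume with majority vote", {
  pts <- rbind(c(0.34, 0.34, 0.34), c(0.35, 0.33, 0.34), c(1.02, 0, 0))
  vol <- labels_to_volume(pts, c(2L, 1L, 3L), dim = c(5, 5, 5),
                          voxel_size = 0.34)
  expect_equal(vol[2, 2, 2], 1L) # tie between 1 and 2 -> smallest
  expect_equal(vol[4, 1, 1], 3L)
  expect_equal(sum(vol > 0), 2)
})

test_that("boundary-hugging clusters are flagged as noise clusters", {
  cfg <- tiny_config()
  fx <- tiny_features()
  tr <- tiny_phantom()$truth
  res <- kmeans_best_of(fx$feats, 2, n_restarts = 10, seed = 23)
  res <- order_clusters_by_depth(res, fx$samp$level)
  pts <- cbind(fx$samp$x, fx$samp$y, fx$samp$z)
  flags <- flag_noise_clusters(res, pts, tr$gm_mask, cfg$voxel_size)
  expect_length(flags, 2)
  # mid-depth laminar clusters are not boundary-dominated on the phantom:
  # a synthetic cluster of pure boundary samples is
  shallow <- fx$samp$level %in% c(0.1, 0.9)
  fake <- res
  fake$labels <- ifelse(shallow, 1L, 2L)
  fake$k <- 2L
  flags2 <- flag_noise_clusters(fake, pts, tr$gm_mask, cfg$voxel_size)
  expect_true(flags2[1])
  expect_false(flags2[2])
})
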