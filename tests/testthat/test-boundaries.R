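# Sliding-block Mahalanobis distances, Hotelling T2 significance,
# multi-scale counting and grid reduction.

test_that("Mahalanobis distance matches direct formula evaluation", {
  # identical blocks: D = 0
  set.seed(31)
  blk <- matrix(rnorm(12), 4, 3)
  d0 <- sliding_mahalanobis(rbind(blk, blk), N = 4)
  expect_equal(d0$D[d0$position == 5], 0)
  # 1D features with pooled variance 1, means 0 vs d: D = d^2
  a <- 1 / sqrt(2) # two-point blocks with sample variance 1
  d <- 3
  row1 <- matrix(c(-a, a, d - a, d + a), 4, 1)
  dm <- sliding_mahalanobis(row1, N = 2)
  expect_equal(dm$D[dm$position == 3], d^2, tolerance = 1e-12)
  # 2D features, identity pooled covariance, mean shift (1,1): D = 2
  s <- sqrt(3 / 2)
  blk <- rbind(c(s, 0), c(-s, 0), c(0, s), c(0, -s))
  row2 <- rbind(blk, sweep(blk, 2, c(1, 1), "+"))
  dm2 <- sliding_mahalanobis(row2, N = 4)
  expect_equal(dm2$D[dm2$position == 5], 2, tolerance = 1e-12)
})

test_that("Mahalanobis agrees with the stats oracle and is affine invariant", {
  set.seed(14)
  L <- 40; p <- 5; N <- 8
  x <- matrix(rnorm(L * p), L, p)
  dm <- sliding_mahalanobis(x, N)
  i <- 12
  b1 <- x[(i - N):(i - 1), ]; b2 <- x[i:(i + N - 1), ]
  C <- (cov(b1) + cov(b2)) / 2
  ref <- stats::mahalanobis(t(colMeans(b1)), colMeans(b2), C)
  expect_equal(dm$D[dm$position == i], as.numeric(ref), tolerance = 1e-10)
  # full-rank affine transform of the features leaves D unchanged
  A <- matrix(rnorm(p * p), p, p) + diag(p) * 2
  y <- x %*% A + matrix(rep(rnorm(p), each = L), L, p)
  dmy <- sliding_mahalanobis(y, N)
  expect_equal(dmy$D, dm$D, tolerance = 1e-8)
})

test_that("Hotelling transform, dof and guard rails", {
  ht <- hotelling_significance(0, 12, 12, p = 12, n_tests = 10)
  expect_equal(ht$T2, 0)
  expect_equal(ht$p_value, 1)
  expect_false(ht$significant)
  # N1 = N2 = 12, p = 12: F dof are (12, 11)
  D <- 4
  ht2 <- hotelling_significance(D, 12, 12, p = 12, n_tests = 1)
  T2 <- (12 * 12 / 24) * D
  Fst <- T2 * 11 / (12 * 22)
  expect_equal(ht2$F, Fst)
  expect_equal(ht2$p_value, pf(Fst, 12, 11, lower.tail = FALSE))
  expect_error(hotelling_significance(1, 6, 6, p = 12),
               "minimum equal block size")
})

test_that("family-wise false-positive rate is controlled under the null", {
  # homogeneous rows: no position should be declared significant at level
  # alpha after Bonferroni over (position x block size) tests
  set.seed(15)
  n_reps <- 500
  L <- 60
  block_range <- 12:24
  n_tests <- sum(pmax(0, L - 2 * block_range + 1))
  false_pos <- 0
  for (r in seq_len(n_reps)) {
    x <- matrix(rnorm(L * 12), L, 12)
    any_sig <- FALSE
    for (N in block_range) {
      dm <- sliding_mahalanobis(x, N)
      ht <- hotelling_significance(dm$D, N, N, p = 12, n_tests = n_tests)
      if (any(ht$significant)) { any_sig <- TRUE; break }
    }
    false_pos <- false_pos + any_sig
  }
  expect_lte(false_pos / n_reps, 0.05)
})

test_that("latero-medial averaging reduces and cancels as specified", {
  mk_grid <- function(features, mask = NULL) {
    dims <- dim(features)
    structure(list(dims = c(dims[1], dims[2], 9L), features = features,
                   mask = if (is.null(mask)) matrix(TRUE, dims[1], dims[2])
                   else mask,
                   levels = seq(0.1, 0.9, 0.1)),
              class = "cortical_grid")
  }
  f <- array(rnorm(100 * 20 * 12), c(100, 20, 12))
  g <- mk_grid(f)
  avg <- average_lateromedial(g, block = 10)
  expect_equal(avg$dims[1:2], c(10, 20))
  # all-identical rows: averaging is the identity
  fid <- array(rep(f[1, , ], each = 100), c(100, 20, 12))
  expect_equal(average_lateromedial(mk_grid(fid), 10)$features[3, , ],
               f[1, , ])
  # alternating (v, -v) rows with block 2 cancel to zero
  v <- rnorm(12)
  fpm <- array(NA_real_, c(4, 5, 12))
  for (i in 1:4) for (j in 1:5) fpm[i, j, ] <- v * (-1)^i
  expect_true(all(abs(average_lateromedial(mk_grid(fpm), 2)$features) < 1e-12))
  # indivisible dimension is an explicit error
  expect_error(average_lateromedial(g, block = 7), "not divisible")
  # masked columns are excluded with count tracking
  msk <- matrix(TRUE, 4, 5); msk[2, 3] <- FALSE
  f2 <- array(1, c(4, 5, 12)); f2[2, 3, ] <- NA
  avg2 <- average_lateromedial(mk_grid(f2, msk), 2)
  expect_equal(avg2$counts[1, 3], 1L)
  expect_equal(avg2$features[1, 3, ], rep(1, 12))
})

test_that("count thresholding merges runs and handles the empty case", {
  det <- data.frame(row = 1, N = 12,
                    position = c(5, 5, 5, 6, 6, 20, 40),
                    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                                    FALSE))
  res <- count_and_threshold(det, n_positions = 50, sd_multiplier = 4.5)
  expect_equal(res$counts[5], 3L)
  expect_equal(res$counts[6], 2L)
  expect_equal(sum(res$counts), 6L)
  # block sizes 12..24: thirteen scales feed the counts
  expect_length(12:24, 13)
  # all-zero counts: explicit empty result
  none <- count_and_threshold(det[det$position == 99, ], 50)
  expect_length(none$boundaries, 0)
  expect_equal(sum(none$counts), 0L)
  # a dominant run is merged and reported at its count maximum
  det2 <- data.frame(row = rep(1:13, each = 3), N = 12,
                     position = rep(c(24, 25, 26), 13),
                     significant = TRUE)
  det2$significant[det2$position == 25] <- TRUE
  res2 <- count_and_threshold(det2, n_positions = 200)
  expect_equal(nrow(res2$runs), 1)
  expect_true(res2$runs$peak %in% 24:26)
})
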