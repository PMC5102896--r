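# Observer-independent cortical area boundaries: a regular tangential lattice
# of depth profiles over the ribbon, latero-medial averaging, sliding-block
# Mahalanobis distances between neighbouring blocks of depth-profile feature
# vectors, Hotelling T2 significance with Bonferroni correction, and
# multi-scale significance counting with SD thresholding.

#' Build the cortical sampling grid of depth-profile features
#'
#' Lays a regular (latero-medial x antero-posterior) lattice of streamline
#' depth profiles over the cortex. Each lattice column is traced through the
#' depth field, sampled at the depth levels, turned into per-depth
#' total/radial/tangential diffusivities (local-frame SH fit) and summarised
#' by the 12 depth-profile moment features. Columns whose streamline does not
#' span both boundaries are masked, not silently filled.
#'
#' @param field A [solve_laplace()] result.
#' @param dwi A `dwi_volume`.
#' @param seeds Array of lattice seed points, dim = c(n_lm, n_ap, 3), world
#'   mm (e.g. from [phantom_grid_seeds()]).
#' @param levels Depth fractions (default 9 levels, 0.1 to 0.9).
#' @param max_order SH order for the diffusivity summaries.
#' @param sampling Optional `depth_sampling` from a previous [build_grid()]
#'   call on the same field/seeds (attached to its result as `sampling`);
#'   streamline tracing is noise-independent, so re-analyses of new noise
#'   realisations can reuse it.
#' @return Object of class `cortical_grid`: `dims` (n_lm, n_ap, n_levels),
#'   `features` (n_lm x n_ap x 12 array), `mask` (n_lm x n_ap, TRUE =
#'   complete profile), `profiles` (n_lm x n_ap x n_levels x 3 diffusivity
#'   array), `levels`, `seeds`, `sampling`.
#' @export
build_grid <- function(field, dwi, seeds, levels = seq(0.1, 0.9, by = 0.1),
                       max_order = 6, sampling = NULL) {
  stopifnot(length(dim(seeds)) == 3L, dim(seeds)[3] == 3L)
  n_lm <- dim(seeds)[1]
  n_ap <- dim(seeds)[2]
  seed_mat <- cbind(as.vector(seeds[, , 1]), as.vector(seeds[, , 2]),
                    as.vector(seeds[, , 3]))
  samp <- if (is.null(sampling)) {
    prof <- trace_streamlines(field, seed_mat)
    sample_depth_levels(prof, field, levels = levels)
  } else sampling
  sig <- sample_signal_at_locations(dwi, cbind(samp$x, samp$y, samp$z))
  if (length(sig$kept) < nrow(samp)) {
    keep <- seq_len(nrow(samp)) %in% sig$kept
    samp <- samp[keep, , drop = FALSE]
  }
  feats <- layer_feature_matrix(sig$signal, sig$s0, sig$dirs, sig$b,
                                as.matrix(samp[, c("nx", "ny", "nz")]),
                                max_order = max_order)

  nl <- length(levels)
  profiles <- array(NA_real_, dim = c(n_lm, n_ap, nl, 3L))
  col_of <- samp$profile                     # linear lattice index
  lev_of <- match(samp$level, levels)
  for (j in 1:3)
    profiles[cbind(((col_of - 1) %% n_lm) + 1,
                   ((col_of - 1) %/% n_lm) + 1, lev_of, j)] <- feats[, j]

  features <- array(NA_real_, dim = c(n_lm, n_ap, 12L))
  mask <- matrix(FALSE, n_lm, n_ap)
  for (i in seq_len(n_lm)) for (j in seq_len(n_ap)) {
    pr <- profiles[i, j, , ]
    if (anyNA(pr)) next
    features[i, j, ] <- depth_profile_moments(pr)
    mask[i, j] <- TRUE
  }
  structure(list(dims = c(n_lm, n_ap, nl), features = features, mask = mask,
                 profiles = profiles, levels = levels, seeds = seeds,
                 sampling = samp),
            class = "cortical_grid")
}

#' Lattice seed points on the phantom mid-cortex surface
#'
#' A (latero-medial x antero-posterior) lattice at mid-cortical radius:
#' antero-posterior follows the angular coordinate of the half-annulus,
#' latero-medial follows the extrusion (z) axis.
#'
#' @param config A [phantom_config()].
#' @param n_lm,n_ap Lattice dimensions (default 100 x 200).
#' @param theta_margin Angular margin (radians) avoided at the ribbon's cut
#'   ends.
#' @param z_margin_mm Margin along the extrusion axis (mm).
#' @return Array dim = c(n_lm, n_ap, 3) of world-mm seeds, plus attributes
#'   `theta` (per ap position) and `z` (per lm position).
#' @export
phantom_grid_seeds <- function(config, n_lm = 100L, n_ap = 200L,
                               theta_margin = 0.2, z_margin_mm = 1.0) {
  r_mid <- (config$inner_radius + config$outer_radius) / 2
  theta <- seq(theta_margin, pi - theta_margin, length.out = n_ap)
  zmax <- (config$volume_shape[3] - 1) * config$voxel_size
  z <- seq(z_margin_mm, zmax - z_margin_mm, length.out = n_lm)
  seeds <- array(NA_real_, dim = c(n_lm, n_ap, 3L))
  for (j in seq_len(n_ap)) {
    seeds[, j, 1] <- config$center_xy[1] + r_mid * cos(theta[j])
    seeds[, j, 2] <- config$center_xy[2] + r_mid * sin(theta[j])
    seeds[, j, 3] <- z
  }
  attr(seeds, "theta") <- theta
  attr(seeds, "z") <- z
  seeds
}

#' Latero-medial averaging of the grid
#'
#' Feature-wise mean over non-overlapping blocks of adjacent latero-medial
#' rows (masked columns are excluded from the mean, with count tracking).
#' Increases boundary-detection sensitivity by noise averaging.
#'
#' @param grid A `cortical_grid`.
#' @param block Rows per block (default 10); the latero-medial dimension must
#'   be divisible by it.
#' @return A reduced `cortical_grid` with dims (n_lm/block, n_ap, levels);
#'   `counts` records contributing rows per averaged cell.
#' @export
average_lateromedial <- function(grid, block = 10L) {
  stopifnot(inherits(grid, "cortical_grid"))
  n_lm <- grid$dims[1]
  if (n_lm %% block != 0)
    stop(sprintf("latero-medial dimension %d not divisible by block %d",
                 n_lm, block))
  n_out <- n_lm %/% block
  n_ap <- grid$dims[2]
  features <- array(NA_real_, dim = c(n_out, n_ap, 12L))
  counts <- matrix(0L, n_out, n_ap)
  for (r in seq_len(n_out)) {
    rows <- ((r - 1) * block + 1):(r * block)
    sub <- grid$features[rows, , , drop = FALSE]
    ok <- grid$mask[rows, , drop = FALSE]
    for (j in seq_len(n_ap)) {
      use <- ok[, j]
      counts[r, j] <- sum(use)
      if (any(use))
        features[r, j, ] <- colMeans(matrix(sub[use, j, , drop = FALSE],
                                            nrow = sum(use)))
    }
  }
  out <- grid
  out$dims <- c(n_out, n_ap, grid$dims[3])
  out$features <- features
  out$mask <- counts > 0
  out$counts <- counts
  out$profiles <- NULL
  out$seeds <- NULL
  out
}

#' Sliding-block Mahalanobis distance along a feature row
#'
#' At each antero-posterior position i the mean feature vectors of the two
#' adjacent blocks of N profiles, [i-N, i-1] and [i, i+N-1], are compared by
#' D = (x1 - x2) C^-1 (x1 - x2)' with C the pooled within-block covariance
#' (2N - 2 degrees of freedom). A singular C is ridge-regularised by
#' eps * trace(C)/p on the diagonal and flagged.
#'
#' @param row_features L x p matrix (one averaged lattice row; p = 12).
#' @param N Block size; requires L >= 2N.
#' @param ridge_eps Ridge fraction used when C is singular.
#' @return data.frame with `position` (block junction index i, in
#'   N+1 .. L-N+1), `D`, and `ridged` flag.
#' @export
sliding_mahalanobis <- function(row_features, N, ridge_eps = 1e-6) {
  x <- as.matrix(row_features)
  L <- nrow(x)
  p <- ncol(x)
  if (L < 2 * N) stop("row length must be at least 2N")
  positions <- (N + 1):(L - N + 1)
  D <- numeric(length(positions))
  ridged <- logical(length(positions))
  for (q in seq_along(positions)) {
    i <- positions[q]
    b1 <- x[(i - N):(i - 1), , drop = FALSE]
    b2 <- x[i:(i + N - 1), , drop = FALSE]
    m1 <- colMeans(b1)
    m2 <- colMeans(b2)
    diff <- m1 - m2
    if (all(diff == 0)) { # identical block means: D = 0 by definition
      D[q] <- 0
      next
    }
    C <- ((N - 1) * stats::cov(b1) + (N - 1) * stats::cov(b2)) / (2 * N - 2)
    sol <- tryCatch(solve(C, diff), error = function(e) NULL)
    if (is.null(sol)) {
      C <- C + diag(max(ridge_eps * sum(diag(C)) / p,
                        .Machine$double.xmin), p)
      sol <- tryCatch(solve(C, diff), error = function(e) NULL)
      if (is.null(sol)) sol <- as.numeric(MASS::ginv(C) %*% diff)
      ridged[q] <- TRUE
    }
    D[q] <- sum(diff * sol)
  }
  data.frame(position = positions, D = D, ridged = ridged)
}

#' Hotelling T2 significance of block-mean differences
#'
#' T2 = (N1 N2 / (N1 + N2)) D, transformed to
#' F = T2 (N1 + N2 - p - 1) / (p (N1 + N2 - 2)) with (p, N1 + N2 - p - 1)
#' degrees of freedom; significance at alpha / n_tests (Bonferroni).
#'
#' @param D Mahalanobis distances (vector).
#' @param N1,N2 Block sizes.
#' @param p Feature dimension (default 12).
#' @param n_tests Bonferroni family size.
#' @param alpha Family-wise level (default 0.05).
#' @return data.frame with `T2`, `F`, `p_value`, `significant`.
#' @export
hotelling_significance <- function(D, N1, N2, p = 12, n_tests = 1,
                                   alpha = 0.05) {
  df2 <- N1 + N2 - p - 1
  if (df2 < 1)
    stop(sprintf(
      "degrees-of-freedom violation: N1 + N2 - p - 1 = %d < 1; minimum equal block size is %d",
      df2, ceiling((p + 2) / 2)))
  T2 <- (N1 * N2 / (N1 + N2)) * D
  Fst <- T2 * df2 / (p * (N1 + N2 - 2))
  pv <- stats::pf(Fst, p, df2, lower.tail = FALSE)
  data.frame(T2 = T2, F = Fst, p_value = pv,
             significant = pv < alpha / n_tests)
}

#' Multi-scale significance counting and SD thresholding
#'
#' Sums significant detections per antero-posterior position over all block
#' sizes and lattice rows, thresholds the counts at
#' mean + `sd_multiplier` * SD, and merges super-threshold positions into
#' runs whose count-maximum is reported as the boundary location.
#'
#' @param detections data.frame with columns `row`, `N`, `position`,
#'   `significant` (one row per test).
#' @param n_positions Number of antero-posterior grid positions.
#' @param sd_multiplier Threshold multiplier (default 4.5).
#' @return Object of class `boundary_result`: `counts` (per position),
#'   `threshold`, `boundaries` (positions), `runs` (data.frame of merged
#'   runs), `detections`.
#' @export
count_and_threshold <- function(detections, n_positions,
                                sd_multiplier = 4.5) {
  counts <- integer(n_positions)
  if (nrow(detections)) {
    tab <- table(factor(detections$position[detections$significant],
                        levels = seq_len(n_positions)))
    counts <- as.integer(tab)
  }
  threshold <- mean(counts) + sd_multiplier * stats::sd(counts)
  if (!is.finite(threshold)) threshold <- Inf
  above <- which(counts > threshold)
  runs <- data.frame(start = integer(0), end = integer(0),
                     peak = integer(0), peak_count = integer(0))
  if (length(above)) {
    brk <- c(0, which(diff(above) > 1), length(above))
    for (q in seq_len(length(brk) - 1)) {
      seg <- above[(brk[q] + 1):brk[q + 1]]
      peak <- seg[which.max(counts[seg])]
      runs <- rbind(runs, data.frame(start = seg[1], end = seg[length(seg)],
                                     peak = peak,
                                     peak_count = counts[peak]))
    }
  }
  structure(list(counts = counts, threshold = threshold,
                 boundaries = runs$peak, runs = runs,
                 sd_multiplier = sd_multiplier, detections = detections),
            class = "boundary_result")
}

#' @export
print.boundary_result <- function(x, ...) {
  cat(sprintf("boundary detection: threshold %.2f (mean + %.1f SD)\n",
              x$threshold, x$sd_multiplier))
  if (length(x$boundaries))
    cat("boundaries at antero-posterior positions:",
        paste(x$boundaries, collapse = ", "), "\n")
  else cat("no boundaries detected\n")
  invisible(x)
}

#' End-to-end area-boundary detection on a grid
#'
#' Latero-medial averaging, then for every averaged row and block size N the
#' sliding Mahalanobis distances and Hotelling/Bonferroni significance, then
#' multi-scale counting with SD thresholding. The Bonferroni family is the
#' total number of (position, block size) tests per row; rows act as
#' replicates that feed the counts, not as extra tests.
#'
#' @param grid A `cortical_grid` (full resolution).
#' @param block_range Block sizes N (default 12:24).
#' @param lm_block Latero-medial averaging block (default 10).
#' @param sd_multiplier Count threshold multiplier (default 4.5).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `boundary_result`; the averaged grid is attached as
#'   `averaged_grid`.
#' @export
detect_area_boundaries <- function(grid, block_range = 12:24, lm_block = 10L,
                                   sd_multiplier = 4.5, alpha = 0.05) {
  avg <- average_lateromedial(grid, block = lm_block)
  n_ap <- avg$dims[2]
  n_tests <- sum(vapply(block_range, function(N) {
    max(0, n_ap - 2 * N + 1)
  }, numeric(1)))
  det <- list()
  for (r in seq_len(avg$dims[1])) {
    row_feat <- avg$features[r, , ]
    if (anyNA(row_feat)) next # incomplete rows do not enter the stepping
    for (N in block_range) {
      if (nrow(row_feat) < 2 * N) next
      dm <- sliding_mahalanobis(row_feat, N)
      ht <- hotelling_significance(dm$D, N, N, p = ncol(row_feat),
                                   n_tests = n_tests, alpha = alpha)
      det[[length(det) + 1L]] <- data.frame(
        row = r, N = N, position = dm$position, D = dm$D, T2 = ht$T2,
        p_value = ht$p_value, significant = ht$significant)
    }
  }
  det <- if (length(det)) do.call(rbind, det) else
    data.frame(row = integer(0), N = integer(0), position = integer(0),
               D = numeric(0), T2 = numeric(0), p_value = numeric(0),
               significant = logical(0))
  res <- count_and_threshold(det, n_positions = n_ap,
                             sd_multiplier = sd_multiplier)
  res$averaged_grid <- avg
  res$block_range <- block_range
  res
}
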