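# Layer clustering: restarted squared-Euclidean k-means on the
# (locations x depth levels) x 31 feature matrix, silhouette-guided choice of
# k, depth-ordered relabelling and mode-filter label upsampling.

# Z-score columns; constant columns map to zero. Scaling parameters are
# returned so centroids can be expressed on the raw scale.
#' @keywords internal
standardize_features <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, sd, "/"), mean = mu, sd = sd)
}

#' Best-of-n restarted k-means
#'
#' Squared-Euclidean (Lloyd) k-means with random centroid initialisation per
#' restart; the solution minimising the within-cluster sum of squared
#' distances over all restarts is kept. Restarts that converge with an empty
#' cluster are discarded and redrawn. Features are z-scored per column before
#' clustering (diffusivities and SH coefficients live on very different
#' scales); no spatial or depth information enters the feature matrix.
#'
#' @param features Rows x features numeric matrix (finite).
#' @param k Number of clusters (>= 2, <= rows).
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Integer seed; fixes the whole restart sequence.
#' @param iter_max Lloyd iteration cap per restart.
#' @param standardize Z-score columns first (default TRUE).
#' @return Object of class `cluster_result`: `k`, `labels` (1..k), `centers`
#'   (k x features, raw scale), `centers_std` (standardised scale),
#'   `objective` (kept run), `objectives` (all restarts), `n_restarts`,
#'   `n_discarded`, `seed`, `scaling`.
#' @export
kmeans_best_of <- function(features, k, n_restarts = 100, seed = NULL,
                           iter_max = 100, standardize = TRUE) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("features must be finite")
  n <- nrow(features)
  if (k < 2 || k > n) stop("k must lie in [2, nrow(features)]")
  sc <- if (standardize) standardize_features(features) else
    list(x = features, mean = rep(0, ncol(features)),
         sd = rep(1, ncol(features)))
  x <- sc$x
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  objectives <- numeric(0)
  n_discarded <- 0L
  r <- 0L
  while (r < n_restarts) {
    centers <- x[sample.int(n, k), , drop = FALSE]
    if (anyDuplicated(centers)) {
      n_discarded <- n_discarded + 1L
      next
    }
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers,
                                     iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (is.null(km) || any(km$size == 0)) {
      n_discarded <- n_discarded + 1L
      next
    }
    r <- r + 1L
    objectives <- c(objectives, km$tot.withinss)
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  centers_raw <- sweep(sweep(best$centers, 2, sc$sd, "*"), 2, sc$mean, "+")
  structure(list(
    k = k, labels = as.integer(best$cluster), centers = centers_raw,
    centers_std = best$centers, objective = best$tot.withinss,
    objectives = objectives, n_restarts = n_restarts,
    n_discarded = n_discarded, seed = seed, scaling = sc[c("mean", "sd")]
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("k-means result: k = %d, n = %d, objective = %.4g (best of %d restarts)\n",
              x$k, length(x$labels), x$objective, x$n_restarts))
  invisible(x)
}

#' Silhouette values for a labelled set
#'
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)) where a(i) is the mean
#' dissimilarity of i to its own cluster's other members and b(i) the lowest
#' mean dissimilarity to any other cluster. Members of singleton clusters
#' (and fully degenerate points with a = b = 0) score 0.
#'
#' @param x Rows x features matrix.
#' @param labels Integer cluster labels.
#' @return Numeric vector of silhouette values in [-1, 1].
#' @export
silhouette_values <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  labs <- sort(unique(labels))
  k <- length(labs)
  if (k < 2) stop("silhouette requires at least two clusters")
  D <- as.matrix(stats::dist(x))
  member <- matrix(0, n, k)
  member[cbind(seq_len(n), match(labels, labs))] <- 1
  sums <- D %*% member                 # n x k: summed distance to each cluster
  counts <- colSums(member)
  lab_i <- match(labels, labs)
  a_cnt <- counts[lab_i] - 1
  a <- ifelse(a_cnt > 0, sums[cbind(seq_len(n), lab_i)] / a_cnt, NA)
  mean_to <- sweep(sums, 2, counts, "/")
  mean_to[cbind(seq_len(n), lab_i)] <- Inf
  b <- apply(mean_to, 1, min)
  s <- (b - a) / pmax(a, b)
  s[is.na(a)] <- 0          # singleton policy
  s[!is.finite(s)] <- 0     # a = b = 0 (coincident points)
  unname(s)
}

#' Mean-silhouette curve over candidate cluster numbers
#'
#' For each k in `k_range`, clusters the feature matrix with
#' [kmeans_best_of()] and computes the mean silhouette over a seeded random
#' subsample (the full-matrix silhouette is quadratic in rows). Local maxima
#' of the curve are reported as candidate cluster numbers; an endpoint counts
#' as a maximum when it exceeds its single neighbour.
#'
#' @param features Rows x features matrix.
#' @param k_range Candidate cluster counts (default 2:7).
#' @param n_restarts Restarts per k (default 20 for model selection; the
#'   final clustering at the chosen k should use 100).
#' @param subsample Silhouette subsample size (default 10000).
#' @param seed Integer seed governing restarts and the subsample.
#' @return Object of class `silhouette_curve`: `curve` data.frame
#'   (k, mean_silhouette), `candidates` (local-maximum ks), `subsample_size`,
#'   and the per-k `cluster_results`.
#' @export
silhouette_curve <- function(features, k_range = 2:7, n_restarts = 20,
                             subsample = 10000, seed = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (max(k_range) > n) stop("k_range exceeds the number of rows")
  if (!is.null(seed)) set.seed(seed)
  sub <- if (n > subsample) sort(sample.int(n, subsample)) else seq_len(n)
  seeds <- if (is.null(seed)) rep(list(NULL), length(k_range)) else
    as.list(seed + seq_along(k_range))
  results <- vector("list", length(k_range))
  msil <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    res <- kmeans_best_of(features, k_range[i], n_restarts = n_restarts,
                          seed = seeds[[i]])
    results[[i]] <- res
    labs_sub <- res$labels[sub]
    msil[i] <- if (length(unique(labs_sub)) < 2) 0 else
      mean(silhouette_values(features[sub, , drop = FALSE], labs_sub))
  }
  cand <- local_maxima(msil)
  structure(list(
    curve = data.frame(k = k_range, mean_silhouette = msil),
    candidates = k_range[cand], subsample_size = length(sub),
    cluster_results = results
  ), class = "silhouette_curve")
}

# Indices of local maxima: not below either neighbour, strictly above at
# least one; endpoints are compared against their single neighbour.
#' @keywords internal
local_maxima <- function(y) {
  n <- length(y)
  if (n == 1) return(1L)
  keep <- logical(n)
  for (i in seq_len(n)) {
    left_ok <- i == 1 || y[i] >= y[i - 1]
    right_ok <- i == n || y[i] >= y[i + 1]
    strict <- (i > 1 && y[i] > y[i - 1]) || (i < n && y[i] > y[i + 1])
    keep[i] <- left_ok && right_ok && strict
  }
  which(keep)
}

#' @export
print.silhouette_curve <- function(x, ...) {
  print(x$curve, row.names = FALSE)
  cat("candidate k (local maxima):", paste(x$candidates, collapse = ", "),
      "\n")
  invisible(x)
}

#' Renumber clusters by increasing mean cortical depth
#'
#' Depth is used for labelling only, never for clustering: the partition and
#' objective are unchanged, only the ids are permuted so that cluster 1 is
#' the deepest (nearest the white/gray-matter boundary).
#'
#' @param result A `cluster_result`.
#' @param depths Relative depth of each clustered row.
#' @return The relabelled `cluster_result`, with `mean_depths` attached.
#' @export
order_clusters_by_depth <- function(result, depths) {
  stopifnot(inherits(result, "cluster_result"),
            length(depths) == length(result$labels))
  mean_depth <- tapply(depths, result$labels, mean)
  ord <- order(mean_depth)
  perm <- integer(result$k)
  perm[as.integer(names(mean_depth))[ord]] <- seq_len(result$k)
  out <- result
  out$labels <- perm[result$labels]
  inv <- order(perm)
  out$centers <- result$centers[inv, , drop = FALSE]
  out$centers_std <- result$centers_std[inv, , drop = FALSE]
  out$mean_depths <- as.numeric(sort(mean_depth))
  out
}

#' Flag clusters dominated by tissue-boundary samples
#'
#' Clusters of locations that mostly hug a mask boundary typically reflect
#' partial-volume mixing with white matter or embedding fluid rather than a
#' laminar compartment. A cluster is flagged as a noise cluster when the
#' majority of its members lie within one voxel of a non-gray-matter voxel -
#' an explicit, testable stand-in for qualitative inspection.
#'
#' @param result A `cluster_result`.
#' @param points n x 3 world-mm positions of the clustered rows (one per
#'   label; for multi-depth feature rows, the sampled location).
#' @param gm_mask Logical gray-matter volume.
#' @param voxel_size Isotropic voxel size in mm.
#' @return Logical vector of length k (TRUE = noise cluster), with the
#'   per-cluster boundary fraction as attribute `boundary_fraction`.
#' @export
flag_noise_clusters <- function(result, points, gm_mask, voxel_size) {
  stopifnot(inherits(result, "cluster_result"),
            nrow(points) == length(result$labels))
  interior <- gm_mask & !dilate6(!gm_mask) # GM voxels with all-GM neighbours
  vox <- pmin(pmax(round(world_to_vox0(points, rep(voxel_size, 3))) + 1, 1),
              matrix(dim(gm_mask), nrow(points), 3, byrow = TRUE))
  lin <- vox[, 1] + dim(gm_mask)[1] * (vox[, 2] - 1) +
    prod(dim(gm_mask)[1:2]) * (vox[, 3] - 1)
  near_boundary <- !interior[lin]
  frac <- tapply(near_boundary, result$labels, mean)
  flags <- as.logical(frac > 0.5)
  attr(flags, "boundary_fraction") <- as.numeric(frac)
  flags
}

#' Mode-filtered label upsampling
#'
#' Nearest-neighbour upsampling of an integer label volume by an integer
#' factor, followed by a sliding-window mode filter (default 5 x 5 x 5,
#' truncated at volume edges, ties broken to the smallest label).
#'
#' @param labels Integer 3D array.
#' @param factor Upsampling factor per axis (default 3).
#' @param window Mode-filter window edge length (odd, default 5).
#' @return Integer 3D array of dimension `factor * dim(labels)`.
#' @export
mode_filter_upsample <- function(labels, factor = 3L, window = 5L) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (any(labels != round(labels)))
    stop("type error: labels must be integers")
  d <- dim(labels)
  up <- labels[rep(seq_len(d[1]), each = factor),
               rep(seq_len(d[2]), each = factor),
               rep(seq_len(d[3]), each = factor)]
  du <- dim(up)
  vals <- sort(unique(as.vector(up)))
  if (length(vals) == 1) return(array(as.integer(up), du))
  radius <- (window - 1L) %/% 2L
  best_cnt <- array(-1, du)
  best_lab <- array(vals[1], du)
  for (v in vals) {
    cnt <- box_count(up == v, radius)
    better <- cnt > best_cnt # ties keep the earlier (smaller) label
    best_lab[better] <- v
    best_cnt[better] <- cnt[better]
  }
  array(as.integer(best_lab), du)
}

# Sliding-box sum of a logical array with window radius r, truncated at the
# edges, via separable cumulative sums.
#' @keywords internal
box_count <- function(mask, r) {
  x <- array(as.numeric(mask), dim = dim(mask))
  for (ax in 1:3) x <- box_sum_axis(x, ax, r)
  x
}

#' @keywords internal
box_sum_axis <- function(x, axis, r) {
  d <- dim(x)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = n)
  cs <- rbind(0, apply(m, 2, cumsum))
  hi <- pmin(seq_len(n) + r, n) + 1L
  lo <- pmax(seq_len(n) - r, 1L)
  out <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  xp <- array(out, dim = d[perm])
  aperm(xp, order(perm))
}

#' Paint sampled labels into a voxel volume
#'
#' Assigns each sample's label to its nearest voxel; voxels receiving several
#' samples take the most frequent label (ties to the smallest), voxels with
#' none stay 0.
#'
#' @param points n x 3 world-mm positions.
#' @param labels Integer labels per point.
#' @param dim Volume dimensions.
#' @param voxel_size Isotropic voxel size in mm.
#' @return Integer 3D array.
#' @export
labels_to_volume <- function(points, labels, dim, voxel_size) {
  vox <- round(world_to_vox0(points, rep(voxel_size, 3))) + 1
  keep <- vox[, 1] >= 1 & vox[, 1] <= dim[1] & vox[, 2] >= 1 &
    vox[, 2] <= dim[2] & vox[, 3] >= 1 & vox[, 3] <= dim[3]
  vox <- vox[keep, , drop = FALSE]
  labels <- labels[keep]
  lin <- vox[, 1] + dim[1] * (vox[, 2] - 1) + dim[1] * dim[2] * (vox[, 3] - 1)
  out <- array(0L, dim = dim)
  grp <- split(labels, lin)
  out[as.numeric(names(grp))] <- vapply(grp, int_mode, integer(1))
  out
}
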