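# Agreement statistics between label maps and between runs: contingency
# cross-tables with optimal class matching and chi-squared tests, reference
# layer grouping, nearest-neighbour label downsampling, matched-cluster
# profile correlations, and b0 SNR measurement.

# Optimal one-to-one assignment of the rows of a count table to distinct
# columns, maximising the total matched count. Exhaustive over column
# permutations (class counts here are small, <= 8); exactness is what makes
# the matching observer-independent and brute-force verifiable.
#' @keywords internal
match_classes <- function(tab) {
  k1 <- nrow(tab)
  k2 <- ncol(tab)
  if (k1 > k2) stop("table must have nrow <= ncol for matching")
  if (k2 > 8) stop("class matching supports at most 8 classes")
  perms <- pracma::perms(seq_len(k2))
  best <- NULL
  best_sum <- -Inf
  for (r in seq_len(nrow(perms))) {
    sel <- perms[r, seq_len(k1)]
    s <- sum(tab[cbind(seq_len(k1), sel)])
    if (s > best_sum) {
      best_sum <- s
      best <- sel
    }
  }
  list(assignment = best, matched_total = best_sum)
}

#' Cross-table contingency analysis of two label maps
#'
#' Joint counts over co-labelled locations (label 0 / NA treated as
#' background and dropped), classes matched by maximal-overlap one-to-one
#' assignment, per-class agreement fractions and a Pearson chi-squared test
#' of association with (k1 - 1)(k2 - 1) degrees of freedom.
#'
#' @param labels_a,labels_b Integer label vectors/arrays on the same lattice.
#' @param normalize `"row"` (default): fractions are per class of `labels_a`
#'   (row-normalised); `"col"`: per class of `labels_b`.
#' @return Object of class `contingency_result`: `table` (k1 x k2 counts),
#'   `assignment` (matched column per row class), `fractions` (per matched
#'   class), `mean_fraction`, `chi2`, `dof`, `p_value`, `n`.
#' @export
cross_table <- function(labels_a, labels_b, normalize = c("row", "col")) {
  normalize <- match.arg(normalize)
  a <- as.vector(labels_a)
  b <- as.vector(labels_b)
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  if (!any(keep)) stop("empty overlap between the two label maps")
  a <- a[keep]
  b <- b[keep]
  tab <- table(a, b)
  k1 <- nrow(tab)
  k2 <- ncol(tab)
  transposed <- FALSE
  mt <- if (k1 <= k2) tab else {
    transposed <- TRUE
    t(tab)
  }
  m <- match_classes(unclass(mt))
  denom <- if (normalize == "row") rowSums(mt) else
    colSums(mt)[m$assignment]
  fractions <- unclass(mt)[cbind(seq_len(nrow(mt)), m$assignment)] / denom
  names(fractions) <- rownames(mt)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(
    table = tab, assignment = m$assignment, transposed = transposed,
    fractions = fractions, mean_fraction = mean(fractions),
    chi2 = unname(chi$statistic), dof = unname(chi$parameter),
    p_value = chi$p.value, n = sum(tab), normalize = normalize
  ), class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("cross-table: n = %d, mean matched fraction = %.3f, chi2 = %.4g (dof %d, p = %.3g)\n",
              x$n, x$mean_fraction, x$chi2, x$dof, x$p_value))
  print(x$table)
  invisible(x)
}

#' Merge reference layers into layer-complexes
#'
#' Relabels a reference label volume according to a grouping, e.g. layers
#' {2,3} -> one complex and {5,6} -> another. The grouping must partition the
#' non-background labels present.
#'
#' @param labels Integer label vector/array (0 = background).
#' @param grouping List of integer vectors; group g becomes new label g, in
#'   list order.
#' @return Relabelled object of the same shape; attribute `grouping` records
#'   the mapping.
#' @export
merge_reference_layers <- function(labels, grouping) {
  present <- sort(unique(as.vector(labels)))
  present <- present[present > 0]
  flat <- unlist(grouping)
  if (anyDuplicated(flat)) stop("overlapping groups in grouping")
  if (!setequal(flat, present))
    stop("grouping must partition the labels present")
  map <- integer(max(present))
  for (g in seq_along(grouping)) map[grouping[[g]]] <- g
  out <- labels
  pos <- which(labels > 0)
  out[pos] <- map[labels[pos]]
  attr(out, "grouping") <- grouping
  out
}

#' Nearest-neighbour label downsampling onto a target grid
#'
#' Maps each target voxel centre through the two affines into the source
#' grid and takes the label of the nearest source voxel. No interpolation:
#' labels remain from the original set.
#'
#' @param labels Integer 3D source array.
#' @param src_affine 4 x 4 voxel(0-based)-to-world affine of the source.
#' @param target_dim Target grid dimensions.
#' @param target_affine 4 x 4 voxel-to-world affine of the target.
#' @return Integer 3D array on the target grid (0 where the target voxel
#'   falls outside the source).
#' @export
downsample_labels_nn <- function(labels, src_affine, target_dim,
                                 target_affine) {
  d <- dim(labels)
  tg <- expand.grid(i = seq_len(target_dim[1]) - 1,
                    j = seq_len(target_dim[2]) - 1,
                    k = seq_len(target_dim[3]) - 1)
  world <- t(target_affine %*% rbind(t(as.matrix(tg)), 1))[, 1:3]
  src <- t(solve(src_affine) %*% rbind(t(world), 1))[, 1:3]
  sv <- round(src) + 1
  inb <- sv[, 1] >= 1 & sv[, 1] <= d[1] & sv[, 2] >= 1 & sv[, 2] <= d[2] &
    sv[, 3] >= 1 & sv[, 3] <= d[3]
  if (!any(inb)) stop("non-overlapping grids")
  out <- integer(nrow(sv))
  lin <- sv[inb, 1] + d[1] * (sv[inb, 2] - 1) + d[1] * d[2] * (sv[inb, 3] - 1)
  out[inb] <- labels[lin]
  array(out, dim = target_dim)
}

#' Scaled voxel-to-world affine
#'
#' @param voxel_size Per-axis voxel size (recycled to length 3).
#' @param origin World position of voxel (0, 0, 0).
#' @return 4 x 4 affine matrix.
#' @export
voxel_affine <- function(voxel_size, origin = c(0, 0, 0)) {
  vs <- rep(voxel_size, length.out = 3)
  rbind(cbind(diag(vs), origin), c(0, 0, 0, 1))
}

#' Pearson correlation of matched cluster profiles
#'
#' @param profiles_a,profiles_b k x f matrices of cluster signal/feature
#'   profiles with rows already matched (e.g. both depth-ordered, or matched
#'   via [cross_table()]).
#' @return Numeric vector of per-cluster correlations; zero-variance profiles
#'   yield NA with a warning.
#' @export
cluster_profile_correlation <- function(profiles_a, profiles_b) {
  a <- as.matrix(profiles_a)
  b <- as.matrix(profiles_b)
  stopifnot(all(dim(a) == dim(b)))
  out <- rep(NA_real_, nrow(a))
  for (i in seq_len(nrow(a))) {
    if (stats::sd(a[i, ]) == 0 || stats::sd(b[i, ]) == 0) next
    out[i] <- stats::cor(a[i, ], b[i, ])
  }
  if (anyNA(out)) warning("zero-variance profile: correlation undefined")
  out
}

#' Measure b0 SNR
#'
#' Per-voxel SNR is the mean divided by the standard deviation of the b0
#' signal across repetitions; the summary is its mean and SD within the mask.
#' Noiseless voxels (zero SD) are reported at the cap sentinel.
#'
#' @param b0 4D array of b0 volumes (repetitions last) or a voxels x
#'   repetitions matrix.
#' @param mask Logical volume (or vector) selecting the summary region;
#'   default all voxels.
#' @param cap Sentinel for infinite SNR (default 1e6).
#' @return List: `snr` (per-voxel array/vector), `mean`, `sd`, `n_b0`.
#' @export
measure_snr <- function(b0, mask = NULL, cap = 1e6) {
  if (is.array(b0) && length(dim(b0)) == 4) {
    d <- dim(b0)
    m <- matrix(b0, prod(d[1:3]), d[4])
    shape <- d[1:3]
  } else {
    m <- as.matrix(b0)
    shape <- NULL
  }
  if (ncol(m) < 3) stop("at least 3 b0 volumes required")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  snr <- ifelse(sdv == 0, cap, mu / sdv)
  snr <- pmin(snr, cap)
  sel <- if (is.null(mask)) rep(TRUE, length(snr)) else as.vector(mask)
  out <- if (is.null(shape)) snr else array(snr, dim = shape)
  list(snr = out, mean = mean(snr[sel]), sd = stats::sd(snr[sel]),
       n_b0 = ncol(m))
}
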