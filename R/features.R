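# Laminar diffusion features: per-direction ADC computation, signal sampling
# at streamline locations, rotation into the local cortical frame, the
# 31-feature layer vector (total/radial/tangential diffusivity + 28 even SH
# coefficients at order 6), and the 12 depth-profile moment features used for
# area-boundary detection.

#' Apparent diffusion coefficient per direction
#'
#' ADC_i = -(1/b) log(S_i / S_0). Noise can push S_i above S_0 or to zero;
#' such samples are flagged and the signal ratio clipped into (`eps`, 1] so
#' downstream fits stay defined. The fraction of flagged samples is carried
#' as an attribute.
#'
#' @param signal Per-direction diffusion-weighted signal (vector or matrix,
#'   directions in columns).
#' @param s0 Non-weighted reference signal (scalar or one per row).
#' @param b b-value in s/mm^2 (> 0).
#' @param clip If TRUE (default) clip the signal ratio to (`eps`, 1]; if
#'   FALSE flagged samples become NA.
#' @param eps Lower clipping bound of the signal ratio.
#' @return ADC values (mm^2/s) with attributes `flagged` (logical, same
#'   shape) and `flagged_fraction`.
#' @export
compute_adc <- function(signal, s0, b, clip = TRUE, eps = 1e-6) {
  if (any(s0 <= 0)) stop("invalid reference: s0 must be positive")
  if (b <= 0) stop("b must be positive")
  ratio <- signal / s0
  flagged <- !is.finite(ratio) | ratio <= 0 | ratio > 1
  if (clip) {
    ratio <- pmin(pmax(ratio, eps), 1)
  } else {
    ratio[flagged] <- NA_real_
  }
  adc <- -log(ratio) / b
  attr(adc, "flagged") <- flagged
  attr(adc, "flagged_fraction") <- mean(flagged)
  adc
}

#' Sample the diffusion signal at arbitrary locations
#'
#' Trilinear interpolation in every diffusion-weighted volume; the b0
#' reference is the mean over all non-weighted volumes, interpolated the same
#' way. Out-of-bounds locations are excluded with a warning.
#'
#' @param dwi A `dwi_volume` (or bare 4D array with `scheme` and
#'   `voxel_size` supplied).
#' @param locations n x 3 matrix of world-mm positions.
#' @param scheme,voxel_size Required if `dwi` is a bare array.
#' @return List: `signal` (kept locations x diffusion directions), `s0`
#'   (vector), `dirs` (directions matrix), `b` (shell b-value), `kept`
#'   (indices of retained locations).
#' @export
sample_signal_at_locations <- function(dwi, locations, scheme = NULL,
                                       voxel_size = NULL) {
  if (inherits(dwi, "dwi_volume")) {
    scheme <- dwi$scheme
    voxel_size <- dwi$voxel_size
    dat <- dwi$data
  } else {
    dat <- dwi
    if (is.null(scheme) || is.null(voxel_size))
      stop("scheme and voxel_size required for a bare array")
  }
  d <- dim(dat)
  pv <- world_to_vox0(locations, voxel_size)
  inb <- pv[, 1] >= 0 & pv[, 1] <= d[1] - 1 & pv[, 2] >= 0 &
    pv[, 2] <= d[2] - 1 & pv[, 3] >= 0 & pv[, 3] <= d[3] - 1
  if (!all(inb)) {
    warning(sprintf("%d locations out of volume bounds excluded", sum(!inb)))
    pv <- pv[inb, , drop = FALSE]
  }
  dwi_i <- dwi_indices(scheme)
  b0_i <- b0_indices(scheme)
  sig <- matrix(NA_real_, nrow(pv), length(dwi_i))
  for (m in seq_along(dwi_i))
    sig[, m] <- interp3(array(dat[, , , dwi_i[m]], d[1:3]), pv)
  s0 <- 0
  for (m in b0_i)
    s0 <- s0 + interp3(array(dat[, , , m], d[1:3]), pv)
  s0 <- s0 / length(b0_i)
  list(signal = sig, s0 = s0,
       dirs = scheme$bvecs[dwi_i, , drop = FALSE],
       b = unique(scheme$bvals[dwi_i])[1], kept = which(inb))
}

#' Minimal rotation taking a unit vector to +z
#'
#' Rodrigues rotation about `normal x z`. For `normal` already at +z the
#' identity is returned; for -z, a 180-degree rotation about the x-axis
#' (any tangential axis is equivalent for even, antipodally symmetric
#' profiles).
#'
#' @param normal Unit 3-vector.
#' @return 3 x 3 rotation matrix R with R %*% normal = c(0, 0, 1).
#' @export
rotation_to_z <- function(normal) {
  nrm <- sqrt(sum(normal^2))
  if (nrm < 1e-12) stop("zero normal vector")
  n <- normal / nrm
  cth <- n[3]
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) return(diag(c(1, -1, -1)))
  a <- c(n[2], -n[1], 0) # n x z
  s <- sqrt(sum(a^2))
  ax <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + ax + ax %*% ax * ((1 - cth) / s^2)
}

#' Rotate an ADC profile into the local cortical frame
#'
#' Re-expresses the sampling directions in a frame whose z-axis is the local
#' cortical surface normal; ADC values are unchanged. Downstream SH fits on
#' the rotated directions are therefore performed in the cortical frame.
#'
#' @param dirs n x 3 direction matrix (scanner frame).
#' @param normal Local unit surface normal.
#' @return n x 3 matrix of directions in the cortical frame.
#' @export
rotate_to_cortical_frame <- function(dirs, normal) {
  dirs %*% t(rotation_to_z(normal))
}

# Equatorial-mean backends for the tangential diffusivity: 36-point
# quadrature of the fitted expansion, or the analytic reduction (only m = 0
# terms survive averaging over phi, weighted by P_l(0)).
#' @keywords internal
equator_dirs <- function(n = 36) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cos(phi), sin(phi), 0)
}

#' @keywords internal
sh_equatorial_mean <- function(coef, max_order,
                               backend = c("quadrature", "analytic")) {
  backend <- match.arg(backend)
  if (backend == "quadrature")
    return(mean(sh_eval(coef, equator_dirs(36), max_order = max_order)))
  out <- 0
  for (l in seq(0, max_order, by = 2)) {
    nl0 <- sqrt((2 * l + 1) / (4 * pi))
    pl0 <- pracma::legendre(l, 0)[1]
    out <- out + coef[sprintf("l%dm0", l)] * nl0 * pl0
  }
  unname(out)
}

#' Extract the 31-feature layer vector from a local-frame SH fit
#'
#' Features, in frozen order: (1) total cortical diffusivity, the spherical
#' mean of the fitted profile (from the l = 0 term, or the raw sample mean);
#' (2) radial diffusivity, the fitted ADC along the local normal (+z in the
#' local frame); (3) tangential diffusivity, the mean fitted ADC over the
#' equatorial plane; (4-31) the 28 even SH coefficients at order 6.
#'
#' @param fit An `sh_fit` at order 6, performed on local-frame directions.
#' @param raw_values Optional raw ADC samples; used when
#'   `total_from = "raw"`.
#' @param total_from `"sh"` (spherical mean of the expansion; default) or
#'   `"raw"` (arithmetic mean of the samples).
#' @param tangential_backend Passed to the equatorial mean; both backends
#'   agree to quadrature exactness.
#' @return Named numeric vector of length 31: `total`, `radial`,
#'   `tangential`, then the coefficient names.
#' @export
extract_layer_features <- function(fit, raw_values = NULL,
                                   total_from = c("sh", "raw"),
                                   tangential_backend = "quadrature") {
  stopifnot(inherits(fit, "sh_fit"))
  total_from <- match.arg(total_from)
  cf <- fit$coefficients
  total <- if (total_from == "raw") {
    if (is.null(raw_values)) stop("raw_values required for total_from = 'raw'")
    mean(raw_values)
  } else {
    unname(cf["l0m0"]) / sqrt(4 * pi)
  }
  radial <- 0
  for (l in seq(0, fit$max_order, by = 2))
    radial <- radial + cf[sprintf("l%dm0", l)] * sqrt((2 * l + 1) / (4 * pi))
  tangential <- sh_equatorial_mean(cf, fit$max_order,
                                   backend = tangential_backend)
  out <- c(total = total, radial = unname(radial), tangential = tangential,
           cf)
  out
}

#' Batch layer-feature extraction at sampled locations
#'
#' For each location: compute the ADC profile, rotate the sampling directions
#' into the local cortical frame, fit the even SH basis there and extract the
#' 31 layer features. The per-location design matrices differ (each location
#' has its own rotation), so fits are performed location-wise.
#'
#' @param signal Locations x directions signal matrix.
#' @param s0 Reference b0 signal per location.
#' @param dirs Directions (scanner frame).
#' @param b Shell b-value.
#' @param normals Locations x 3 unit normals.
#' @param max_order Even SH order (default 6).
#' @param total_from See [extract_layer_features()].
#' @return Locations x 31 feature matrix (named columns); attribute
#'   `flagged_fraction` reports the clipped-ADC rate.
#' @export
layer_feature_matrix <- function(signal, s0, dirs, b, normals, max_order = 6,
                                 total_from = "sh", chunk = 1000L) {
  n <- nrow(signal)
  nd <- nrow(dirs)
  stopifnot(nrow(normals) == n, ncol(signal) == nd)
  adc <- compute_adc(signal, s0, b)
  flag_frac <- attr(adc, "flagged_fraction")
  K <- sh_coef_count(max_order)
  if (nd < K)
    stop(sprintf("rank error: %d directions cannot determine %d coefficients",
                 nd, K))

  # Precomputed linear summaries of the coefficient vector: spherical mean
  # (l = 0 term), value at +z, and the 36-point equatorial mean.
  eq_row <- colMeans(sh_basis(equator_dirs(36), max_order))
  z_row <- as.numeric(sh_basis(matrix(c(0, 0, 1), 1), max_order))
  tot_row <- c(1 / sqrt(4 * pi), rep(0, K - 1))

  feats <- matrix(NA_real_, n, 3 + K)
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    m <- hi - lo + 1L
    # rotate the shared direction set into each location's cortical frame and
    # build one stacked basis for the whole chunk
    rot <- matrix(NA_real_, m * nd, 3L)
    for (q in seq_len(m)) {
      rot[((q - 1L) * nd + 1L):(q * nd), ] <-
        dirs %*% t(rotation_to_z(normals[lo + q - 1L, ]))
    }
    B <- sh_basis(rot, max_order)
    for (q in seq_len(m)) {
      rows <- ((q - 1L) * nd + 1L):(q * nd)
      cf <- stats::.lm.fit(B[rows, , drop = FALSE], adc[lo + q - 1L, ])$coefficients
      total <- if (total_from == "raw") mean(adc[lo + q - 1L, ]) else
        sum(tot_row * cf)
      feats[lo + q - 1L, ] <- c(total, sum(z_row * cf), sum(eq_row * cf), cf)
    }
  }
  colnames(feats) <- c("total", "radial", "tangential",
                       colnames(sh_basis(dirs[1, , drop = FALSE], max_order)))
  attr(feats, "flagged_fraction") <- flag_frac
  feats
}

#' Depth-profile moment features
#'
#' For each diffusivity index (total, radial, tangential) over the sampled
#' depth levels: the mean and the central moments of order 2, 3 and 4
#' (population form, divide by n). The "first moment about the mean" is
#' identically zero, so the mean itself is reported in its place, preserving
#' four informative values per index - 12 features in frozen order
#' (total, radial, tangential) x (mean, m2, m3, m4).
#'
#' @param profile Depths x 3 matrix (columns total, radial, tangential), one
#'   complete depth profile.
#' @return Named numeric vector of length 12.
#' @export
depth_profile_moments <- function(profile) {
  profile <- as.matrix(profile)
  stopifnot(ncol(profile) == 3L)
  if (anyNA(profile)) stop("incomplete depth profile")
  idx <- c("total", "radial", "tangential")
  out <- numeric(0)
  for (j in 1:3) {
    x <- profile[, j]
    v <- c(mean(x), central_moment(x, 2), central_moment(x, 3),
           central_moment(x, 4))
    names(v) <- paste0(idx[j], c("_mean", "_m2", "_m3", "_m4"))
    out <- c(out, v)
  }
  out
}
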