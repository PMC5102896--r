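# Streamline depth profiles: integrate the potential's gradient field from
# seed points to both cortical boundaries, giving per-profile arc-length
# depth and equi-depth sample locations with local radial normals.

# One vectorised integration pass for all seeds in one direction
# (sign = +1 toward pial, -1 toward WM). Midpoint (RK2) stepping with
# trilinear gradient interpolation; stops on leaving the GM indicator and
# refines the crossing point by bisection on the interpolated indicator.
#' @keywords internal
trace_one_way <- function(field, seeds, sign, step_mm, max_steps) {
  vs <- field$voxel_size
  gmnum <- array(as.numeric(field$gm_mask), dim = dim(field$gm_mask))
  n <- nrow(seeds)
  pts <- array(NA_real_, dim = c(max_steps + 1L, n, 3L))
  pts[1L, , ] <- seeds
  pos <- seeds
  active <- rep(TRUE, n)
  reached <- rep(FALSE, n)
  n_steps <- rep(0L, n)

  grad_at <- function(p) {
    g <- interp3_vec(field$gradient, world_to_vox0(p, vs), fill = 0)
    normalize_rows(g) * sign
  }
  gm_at <- function(p) {
    v <- interp3(gmnum, world_to_vox0(p, vs), fill = 0)
    v[is.na(v)] <- 0
    v
  }

  for (s in seq_len(max_steps)) {
    if (!any(active)) break
    p <- pos[active, , drop = FALSE]
    g1 <- grad_at(p)
    stalled <- row_norms(g1) < 1e-9
    g2 <- grad_at(p + 0.5 * step_mm * g1)
    zer <- row_norms(g2) < 1e-9
    g2[zer, ] <- g1[zer, , drop = FALSE]
    pnew <- p + step_mm * g2
    inside <- gm_at(pnew) >= 0.5 & !stalled

    ia <- which(active)
    # crossing seeds: bisect between p and pnew on the GM indicator
    crossed <- !inside & !stalled
    if (any(crossed)) {
      lo <- p[crossed, , drop = FALSE]
      hi <- pnew[crossed, , drop = FALSE]
      for (it in 1:10) {
        mid <- (lo + hi) / 2
        ins <- gm_at(mid) >= 0.5
        lo[ins, ] <- mid[ins, , drop = FALSE]
        hi[!ins, ] <- mid[!ins, , drop = FALSE]
      }
      pnew[crossed, ] <- (lo + hi) / 2
      reached[ia[crossed]] <- TRUE
    }
    record <- inside | crossed
    pos[ia[record], ] <- pnew[record, , drop = FALSE]
    pts[s + 1L, ia[record], ] <- pnew[record, , drop = FALSE]
    n_steps[ia[record]] <- s
    active[ia[!inside | stalled]] <- FALSE
  }
  list(points = pts, n_steps = n_steps, reached = reached)
}

#' Trace cortical depth streamlines
#'
#' From each seed, integrates the normalised gradient of the Laplace
#' potential toward the pial boundary and its negation toward the
#' white/gray-matter boundary, using midpoint (second-order) stepping with
#' trilinear interpolation. The two half-traces are joined into one profile
#' running from the WM/GM boundary (relative depth 0) to the pial boundary
#' (1); relative depth along the profile is normalised arc length. Profiles
#' that fail to reach both boundaries within `max_length_mm` are rejected.
#'
#' @param field A [solve_laplace()] result.
#' @param seeds n x 3 matrix of seed points (world mm), inside gray matter.
#' @param step_mm Integration step; default a quarter voxel.
#' @param max_length_mm Rejection bound on streamline length; default 5 times
#'   the nominal cortical thickness implied by the seeds' span, or 5 * 5 mm
#'   when that is degenerate.
#' @return An object of class `streamline_profiles`: list with `polylines`
#'   (list of m x 3 matrices, WM end first), `depths` (list of relative depth
#'   vectors along each polyline), `lengths` (mm), `ok` (logical: reached
#'   both boundaries and within length bound), `seeds`.
#' @export
trace_streamlines <- function(field, seeds, step_mm = NULL,
                              max_length_mm = NULL) {
  stopifnot(inherits(field, "depth_field"), ncol(seeds) == 3L)
  vs <- field$voxel_size
  if (is.null(step_mm)) step_mm <- 0.25 * vs
  if (is.null(max_length_mm)) max_length_mm <- 5 * 5
  max_steps <- ceiling(max_length_mm / step_mm)

  up <- trace_one_way(field, seeds, +1, step_mm, max_steps)
  dn <- trace_one_way(field, seeds, -1, step_mm, max_steps)

  n <- nrow(seeds)
  polylines <- vector("list", n)
  depths <- vector("list", n)
  lengths <- rep(NA_real_, n)
  ok <- up$reached & dn$reached
  for (i in seq_len(n)) {
    if (!ok[i]) next
    down_pts <- dn$points[seq_len(dn$n_steps[i] + 1L), i, , drop = FALSE]
    up_pts <- up$points[seq_len(up$n_steps[i] + 1L), i, , drop = FALSE]
    down_m <- matrix(down_pts, ncol = 3L)
    up_m <- matrix(up_pts, ncol = 3L)
    # WM-first polyline: reversed downward trace then upward trace (seed once)
    poly <- rbind(down_m[rev(seq_len(nrow(down_m))), , drop = FALSE],
                  up_m[-1L, , drop = FALSE])
    seg <- row_norms(diff(poly))
    if (any(seg == 0)) { # drop coincident points (e.g. bisection landing)
      poly <- poly[c(TRUE, seg > 0), , drop = FALSE]
      seg <- row_norms(diff(poly))
    }
    len <- sum(seg)
    if (!is.finite(len) || len <= 0 || len > max_length_mm) {
      ok[i] <- FALSE
      next
    }
    polylines[[i]] <- poly
    depths[[i]] <- c(0, cumsum(seg)) / len
    lengths[i] <- len
  }
  if (any(!ok))
    message(sprintf("%d of %d streamlines rejected (did not span both boundaries)",
                    sum(!ok), n))
  structure(list(polylines = polylines, depths = depths, lengths = lengths,
                 ok = ok, seeds = seeds),
            class = "streamline_profiles")
}

#' Sample profiles at fixed relative cortical depths
#'
#' One location per (profile, level) by linear interpolation of the polyline
#' at the requested normalised arc length; the local normal is the normalised
#' potential gradient at that location. The boundary levels 0 and 1 are
#' excluded by contract (partial-volume avoidance), so levels must lie
#' strictly inside (0, 1).
#'
#' @param profiles A [trace_streamlines()] result.
#' @param field The matching `depth_field` (for normals).
#' @param levels Depth fractions; default `seq(0.1, 0.9, by = 0.1)`.
#' @return An object of class `depth_sampling`: data.frame with columns
#'   `profile`, `level`, `x`, `y`, `z`, `nx`, `ny`, `nz`; attribute `levels`.
#' @export
sample_depth_levels <- function(profiles, field,
                                levels = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(inherits(profiles, "streamline_profiles"))
  if (any(levels <= 0 | levels >= 1))
    stop("levels must lie strictly inside (0, 1)")
  idx <- which(profiles$ok)
  nl <- length(levels)
  out <- vector("list", length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]
    poly <- profiles$polylines[[i]]
    dpt <- profiles$depths[[i]]
    px <- stats::approx(dpt, poly[, 1], xout = levels, ties = "ordered")$y
    py <- stats::approx(dpt, poly[, 2], xout = levels, ties = "ordered")$y
    pz <- stats::approx(dpt, poly[, 3], xout = levels, ties = "ordered")$y
    out[[q]] <- data.frame(profile = i, level = levels,
                           x = px, y = py, z = pz)
  }
  df <- do.call(rbind, out)
  nrm <- normalize_rows(interp3_vec(field$gradient,
                                    world_to_vox0(cbind(df$x, df$y, df$z),
                                                  field$voxel_size)))
  df$nx <- nrm[, 1]; df$ny <- nrm[, 2]; df$nz <- nrm[, 3]
  structure(df, levels = levels, class = c("depth_sampling", "data.frame"))
}
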