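# Laplace-equation cortical depth: a harmonic potential between the
# white/gray-matter boundary (0) and the pial boundary (1), solved on the
# gray-matter voxel grid with a 6-neighbour stencil.

#' Solve the Laplace equation across the cortical ribbon
#'
#' Solves the discrete Dirichlet problem on the gray-matter voxels: the
#' potential is fixed to `wm_value` on white-matter voxels and `pial_value`
#' on pial-side voxels; gray-matter voxels satisfy the 6-neighbour discrete
#' Laplace equation. Neighbours that belong to none of the three masks (or
#' fall outside the volume) are treated as reflecting (homogeneous Neumann),
#' which makes cut faces of a tissue block behave as symmetry planes. The
#' sparse symmetric system is solved directly (Cholesky); `tolerance` is the
#' acceptance bound on the residual of the converged field.
#'
#' Gray-matter components with no path to both boundaries cannot carry a
#' depth value; they are excluded with a warning.
#'
#' @param gm_mask,wm_mask,pial_mask Logical 3D arrays (mutually exclusive).
#' @param voxel_size Isotropic voxel size in mm.
#' @param tolerance Maximum admissible interior residual |Laplacian u|.
#' @param boundary_values Optional numeric 3D array giving per-voxel Dirichlet
#'   values on boundary voxels (overrides `wm_value`/`pial_value`); used e.g.
#'   to benchmark the solver against closed-form solutions.
#' @param wm_value,pial_value Dirichlet constants (defaults 0 and 1).
#' @return An object of class `depth_field`: `potential` (3D array; solved on
#'   GM, boundary values on WM/pial voxels, NA elsewhere), `gradient`
#'   (dim = c(shape, 3), ascent direction of the potential, unnormalised),
#'   masks, `residual` (max interior |Laplacian|), `excluded` (logical array
#'   of dropped GM voxels), `voxel_size`.
#' @export
solve_laplace <- function(gm_mask, wm_mask, pial_mask, voxel_size = 1,
                          tolerance = 1e-6, boundary_values = NULL,
                          wm_value = 0, pial_value = 1) {
  d <- dim(gm_mask)
  stopifnot(length(d) == 3L, all(dim(wm_mask) == d), all(dim(pial_mask) == d))
  if (any(gm_mask & (wm_mask | pial_mask)))
    stop("masks must be mutually exclusive")

  keep <- connected_to_both(gm_mask, wm_mask, pial_mask)
  excluded <- gm_mask & !keep
  if (any(excluded))
    warning(sprintf("%d gray-matter voxels have no path to both boundaries; excluded",
                    sum(excluded)))
  gm <- keep

  idx <- which(gm)
  n <- length(idx)
  if (n == 0) stop("no solvable gray-matter voxels")
  gmid <- array(0L, dim = d)
  gmid[idx] <- seq_len(n)

  bvol <- array(NA_real_, dim = d)
  bvol[wm_mask] <- wm_value
  bvol[pial_mask] <- pial_value
  if (!is.null(boundary_values)) {
    fixed <- wm_mask | pial_mask
    bvol[fixed] <- boundary_values[fixed]
  }

  ai <- as.integer((idx - 1L) %% d[1]) + 1L
  aj <- as.integer(((idx - 1L) %/% d[1]) %% d[2]) + 1L
  ak <- as.integer((idx - 1L) %/% (d[1] * d[2])) + 1L

  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  diag_cnt <- numeric(n)
  rhs <- numeric(n)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (o in seq_len(6)) {
    ni <- ai + offs[o, 1]; nj <- aj + offs[o, 2]; nk <- ak + offs[o, 3]
    inb <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    nidx <- rep(NA_integer_, n)
    nidx[inb] <- ni[inb] + d[1] * (nj[inb] - 1L) +
      d[1] * d[2] * (nk[inb] - 1L)
    is_gm <- inb & gm[ifelse(inb, nidx, 1L)]
    is_dir <- inb & !is_gm & !is.na(bvol[ifelse(inb, nidx, 1L)])
    # gray-matter neighbour: off-diagonal entry
    rows <- c(rows, which(is_gm))
    cols <- c(cols, gmid[nidx[is_gm]])
    vals <- c(vals, rep(-1, sum(is_gm)))
    # Dirichlet neighbour: contributes to the right-hand side
    rhs[is_dir] <- rhs[is_dir] + bvol[nidx[is_dir]]
    diag_cnt <- diag_cnt + as.numeric(is_gm | is_dir)
  }
  A <- Matrix::sparseMatrix(
    i = c(rows, seq_len(n)), j = c(cols, seq_len(n)),
    x = c(vals, diag_cnt), dims = c(n, n)
  )
  u <- as.numeric(Matrix::solve(A, rhs))

  potential <- bvol
  potential[idx] <- u
  res <- max(abs(A %*% u - rhs))
  if (res > tolerance)
    warning(sprintf("Laplace residual %.3g exceeds tolerance %.3g", res,
                    tolerance))

  grad <- potential_gradient(potential, voxel_size)
  structure(list(
    potential = potential, gradient = grad, gm_mask = gm, wm_mask = wm_mask,
    pial_mask = pial_mask, excluded = excluded, residual = res,
    voxel_size = voxel_size
  ), class = "depth_field")
}

#' @export
print.depth_field <- function(x, ...) {
  cat(sprintf("depth field: %d GM voxels, residual %.2e\n",
              sum(x$gm_mask), x$residual))
  invisible(x)
}

# 6-connected flood fill: GM voxels connected (through GM) to both a
# WM-adjacent and a pial-adjacent voxel.
#' @keywords internal
connected_to_both <- function(gm, wm, pial) {
  d <- dim(gm)
  reach <- function(seed_adjacent_to) {
    visited <- array(FALSE, dim = d)
    frontier <- which(gm & dilate6(seed_adjacent_to))
    visited[frontier] <- TRUE
    while (length(frontier)) {
      nb <- neighbours6(frontier, d)
      nb <- nb[!is.na(nb)]
      nb <- nb[gm[nb] & !visited[nb]]
      nb <- unique(nb)
      visited[nb] <- TRUE
      frontier <- nb
    }
    visited
  }
  reach(wm) & reach(pial)
}

# Logical dilation by the 6-neighbourhood.
#' @keywords internal
dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out
}

# Linear indices of the 6 neighbours of each linear index (NA out of bounds).
#' @keywords internal
neighbours6 <- function(idx, d) {
  i <- as.integer((idx - 1L) %% d[1]) + 1L
  j <- as.integer(((idx - 1L) %/% d[1]) %% d[2]) + 1L
  k <- as.integer((idx - 1L) %/% (d[1] * d[2])) + 1L
  lin <- function(ii, jj, kk) {
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    out <- rep(NA_integer_, length(ii))
    out[ok] <- ii[ok] + d[1] * (jj[ok] - 1L) + d[1] * d[2] * (kk[ok] - 1L)
    out
  }
  c(lin(i + 1L, j, k), lin(i - 1L, j, k), lin(i, j + 1L, k),
    lin(i, j - 1L, k), lin(i, j, k + 1L), lin(i, j, k - 1L))
}

# Central-difference gradient of the potential, NA-aware (one-sided at mask
# edges, zero where no valid neighbour pair exists). Returned per mm.
#' @keywords internal
potential_gradient <- function(potential, voxel_size) {
  d <- dim(potential)
  grad <- array(0, dim = c(d, 3L))
  for (ax in 1:3) {
    up <- shift_arr(potential, ax, 1L)
    dn <- shift_arr(potential, ax, -1L)
    ctr <- potential
    g <- (up - dn) / (2 * voxel_size)
    g1 <- (up - ctr) / voxel_size
    g2 <- (ctr - dn) / voxel_size
    g[is.na(g)] <- g1[is.na(g)]
    g[is.na(g)] <- g2[is.na(g)]
    g[is.na(g)] <- 0
    grad[, , , ax] <- g
  }
  grad
}

# Shift an array by one voxel along an axis, padding with NA.
#' @keywords internal
shift_arr <- function(x, axis, by) {
  d <- dim(x)
  out <- array(NA_real_, dim = d)
  src <- lapply(d, seq_len)
  dst <- src
  if (by > 0) {
    src[[axis]] <- seq_len(d[axis] - by) + by
    dst[[axis]] <- seq_len(d[axis] - by)
  } else {
    src[[axis]] <- seq_len(d[axis] + by)
    dst[[axis]] <- seq_len(d[axis] + by) - by
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}
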