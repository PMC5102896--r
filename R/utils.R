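# Internal helpers shared across modules: coordinate conversions, trilinear
# interpolation and small numeric utilities. World coordinates are millimetres
# in a RAS+ frame with the centre of voxel (1,1,1) at the origin, i.e.
# world = (index - 1) * voxel_size.

#' @keywords internal
world_to_vox0 <- function(pts, voxel_size) {
  sweep(pts, 2L, voxel_size, "/")
}

#' @keywords internal
vox0_to_world <- function(pts, voxel_size) {
  sweep(pts, 2L, voxel_size, "*")
}

# Trilinear interpolation of a 3D volume at continuous 0-based voxel
# coordinates. `pts` is an n x 3 matrix. Out-of-bounds points return
# `fill` (default NA). NA voxels propagate into the interpolated value.
#' @keywords internal
interp3 <- function(vol, pts, fill = NA_real_) {
  d <- dim(vol)
  stopifnot(length(d) == 3L, ncol(pts) == 3L)
  n <- nrow(pts)
  out <- rep(fill, n)
  if (n == 0L) return(out)

  x <- pts[, 1L]; y <- pts[, 2L]; z <- pts[, 3L]
  inb <- x >= 0 & x <= d[1L] - 1 & y >= 0 & y <= d[2L] - 1 &
    z >= 0 & z <= d[3L] - 1
  inb[is.na(inb)] <- FALSE
  if (!any(inb)) return(out)
  x <- x[inb]; y <- y[inb]; z <- z[inb]

  x0 <- pmin(floor(x), d[1L] - 2); y0 <- pmin(floor(y), d[2L] - 2)
  z0 <- pmin(floor(z), d[3L] - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0

  # 1-based linear index of the (x0, y0, z0) corner
  i000 <- 1 + x0 + d[1L] * (y0 + d[2L] * z0)
  dx <- 1; dy <- d[1L]; dz <- d[1L] * d[2L]

  v <- vol[i000]           * (1 - fx) * (1 - fy) * (1 - fz) +
    vol[i000 + dx]          * fx       * (1 - fy) * (1 - fz) +
    vol[i000 + dy]          * (1 - fx) * fy       * (1 - fz) +
    vol[i000 + dx + dy]     * fx       * fy       * (1 - fz) +
    vol[i000 + dz]          * (1 - fx) * (1 - fy) * fz +
    vol[i000 + dx + dz]     * fx       * (1 - fy) * fz +
    vol[i000 + dy + dz]     * (1 - fx) * fy       * fz +
    vol[i000 + dx + dy + dz] * fx      * fy       * fz

  out[inb] <- v
  out
}

# Interpolate each component of a vector field stored as dim = c(d, 3).
#' @keywords internal
interp3_vec <- function(field, pts, fill = 0) {
  d <- dim(field)
  stopifnot(length(d) == 4L, d[4L] == 3L)
  cbind(
    interp3(array(field[, , , 1L], d[1:3]), pts, fill),
    interp3(array(field[, , , 2L], d[1:3]), pts, fill),
    interp3(array(field[, , , 3L], d[1:3]), pts, fill)
  )
}

#' @keywords internal
row_norms <- function(m) sqrt(rowSums(m * m))

#' @keywords internal
normalize_rows <- function(m) {
  nrm <- row_norms(m)
  nrm[nrm == 0] <- 1
  m / nrm
}

# Mode of an integer vector with ties broken to the smallest value.
#' @keywords internal
int_mode <- function(x) {
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

# Population central moments about the mean (divide by n).
#' @keywords internal
central_moment <- function(x, order) {
  mean((x - mean(x))^order)
}
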