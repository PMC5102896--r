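# Diffusion gradient schemes: b-values and unit encoding directions for a
# single-shell HARDI acquisition, with b0 volumes first.

#' Create a single-shell diffusion gradient scheme
#'
#' Builds a gradient table with `n_b0` non-weighted volumes followed by
#' `n_directions` unit vectors at the given b-value, spread approximately
#' uniformly over the whole sphere. Two direction generators are available:
#' a deterministic spherical-Fibonacci lattice (default; no optimisation,
#' bit-reproducible) and an electrostatic-repulsion refinement that
#' minimises the Coulomb energy of the antipodally symmetrised point set
#' from a seeded random start.
#'
#' @param n_directions Number of diffusion-weighted directions (>= 6).
#' @param n_b0 Number of non-weighted (b = 0) volumes.
#' @param b_value Diffusion weighting in s/mm^2.
#' @param seed Integer seed for the electrostatic start; ignored by the
#'   Fibonacci generator.
#' @param method `"fibonacci"` or `"electrostatic"`.
#' @return An object of class `gradient_scheme`: a list with `bvals`
#'   (length n_b0 + n_directions), `bvecs` (matrix, one row per volume;
#'   zero rows for b0), and `b_value`.
#' @export
make_gradient_scheme <- function(n_directions, n_b0 = 6L, b_value = 3000,
                                 seed = NULL,
                                 method = c("fibonacci", "electrostatic")) {
  method <- match.arg(method)
  if (n_directions < 6L)
    stop("insufficient directions: at least 6 diffusion directions required")
  dirs <- switch(method,
    fibonacci = fibonacci_directions(n_directions),
    electrostatic = electrostatic_directions(n_directions, seed = seed)
  )
  bvals <- c(rep(0, n_b0), rep(b_value, n_directions))
  bvecs <- rbind(matrix(0, n_b0, 3L), dirs)
  structure(list(bvals = bvals, bvecs = bvecs, b_value = b_value),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("gradient scheme: %d b0 + %d directions at b = %g s/mm^2\n",
              sum(x$bvals == 0), sum(x$bvals > 0), x$b_value))
  invisible(x)
}

#' @keywords internal
dwi_indices <- function(scheme, b0_threshold = 50) {
  which(abs(scheme$bvals) >= b0_threshold)
}

#' @keywords internal
b0_indices <- function(scheme, b0_threshold = 50) {
  which(abs(scheme$bvals) < b0_threshold)
}

# Deterministic whole-sphere spherical-Fibonacci lattice (quadrature grid).
#' @keywords internal
spherical_fibonacci <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (1 - 1 / ((1 + sqrt(5)) / 2)) # golden-angle increments
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Deterministic diffusion-direction fallback: the upper-hemisphere half of a
# 2n-point Fibonacci lattice. Orientations are antipodally symmetric, so a
# hemisphere set avoids the near-antipodal collisions a whole-sphere lattice
# produces after symmetrisation.
#' @keywords internal
fibonacci_directions <- function(n) {
  spherical_fibonacci(2L * n)[seq_len(n), , drop = FALSE]
}

# Electrostatic repulsion on the antipodally symmetrised set: projected
# gradient descent on the Coulomb energy sum_{i<j} 1/|x_i - x_j| including
# each point's antipode. Seeded random start, fixed iteration budget.
#' @keywords internal
electrostatic_directions <- function(n, seed = NULL, n_iter = 300,
                                     step = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::rnorm(3 * n), n, 3)
  x <- normalize_rows(x)
  for (it in seq_len(n_iter)) {
    frc <- matrix(0, n, 3)
    full <- rbind(x, -x)
    for (i in seq_len(n)) {
      dvec <- matrix(x[i, ], 2 * n, 3, byrow = TRUE) - full
      dst2 <- rowSums(dvec^2)
      dst2[dst2 < 1e-12] <- Inf # self and coincident antipode
      frc[i, ] <- colSums(dvec / dst2^1.5)
    }
    x <- normalize_rows(x + step * frc / n)
  }
  x
}

# Minimum pairwise angle (degrees) over the antipodally symmetrised set:
# |dot| folds each pair onto the acute angle between orientations.
#' @keywords internal
min_pairwise_angle <- function(dirs) {
  g <- abs(dirs %*% t(dirs))
  g <- pmin(g, 1)
  acos(max(g[row(g) != col(g)])) * 180 / pi
}
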