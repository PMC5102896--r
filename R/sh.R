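# Real even-order spherical harmonics: basis construction, least-squares
# fitting of ADC profiles, evaluation, and SSE/AIC model-order comparison.
#
# Basis convention (frozen; coefficient vectors must be comparable across
# locations and runs): real SH without the Condon-Shortley phase, even l only,
# ordered l-major ascending with m = -l..l inside each l. For m > 0 the
# function is sqrt(2) N_lm P_lm(cos theta) cos(m phi); for m < 0 the sin
# counterpart; N_lm = sqrt((2l+1)/(4 pi) * (l-|m|)!/(l+|m|)!).

#' Number of even spherical-harmonic coefficients up to a maximum order
#'
#' @param max_order Even non-negative integer.
#' @return Coefficient count: 1, 6, 15, 28, 45 for orders 0, 2, 4, 6, 8.
#' @export
sh_coef_count <- function(max_order) {
  if (max_order %% 2 != 0 || max_order < 0)
    stop("max_order must be an even non-negative integer")
  (max_order / 2 + 1) * (max_order + 1)
}

#' Real even spherical-harmonic design matrix
#'
#' @param dirs n x 3 matrix of unit direction vectors.
#' @param max_order Maximum (even) harmonic order.
#' @return n x K matrix, K = `sh_coef_count(max_order)`, columns named
#'   `l<l>m<m>`.
#' @export
sh_basis <- function(dirs, max_order = 6) {
  stopifnot(ncol(dirs) == 3L)
  if (max_order %% 2 != 0 || max_order < 0)
    stop("max_order must be an even non-negative integer")
  ct <- pmin(pmax(dirs[, 3], -1), 1) # cos(theta)
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  cols <- list()
  nms <- character(0)
  for (l in seq(0, max_order, by = 2)) {
    # pracma::legendre returns (l+1) x n matrix of P_l^m, m = 0..l, with the
    # Condon-Shortley phase; remove it by (-1)^m.
    P <- pracma::legendre(l, ct)
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in -l:l) {
      am <- abs(m)
      nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      plm <- (-1)^am * P[am + 1, ]
      y <- if (m == 0) nlm * plm
      else if (m > 0) sqrt(2) * nlm * plm * cos(m * phi)
      else sqrt(2) * nlm * plm * sin(am * phi)
      cols[[length(cols) + 1L]] <- y
      nms <- c(nms, sprintf("l%dm%d", l, m))
    }
  }
  B <- do.call(cbind, cols)
  colnames(B) <- nms
  B
}

#' Least-squares even spherical-harmonic fit to an ADC profile
#'
#' Fits the real even SH basis to per-direction values by linear least
#' squares and records the sum of squared errors and the Gaussian-form
#' Akaike information criterion, AIC = n log(SSE/n) + 2K.
#'
#' @param values Per-direction ADC samples (length n).
#' @param dirs n x 3 unit direction matrix (same frame as `values`).
#' @param max_order Maximum even order (default 6, i.e. 28 coefficients).
#' @param basis Optional precomputed `sh_basis(dirs, max_order)`.
#' @return Object of class `sh_fit`: `coefficients` (named), `max_order`,
#'   `sse`, `aic`, `n`.
#' @export
fit_even_sh <- function(values, dirs, max_order = 6, basis = NULL) {
  K <- sh_coef_count(max_order)
  if (length(values) < K)
    stop(sprintf("rank error: %d directions cannot determine %d coefficients",
                 length(values), K))
  if (is.null(basis)) basis <- sh_basis(dirs, max_order)
  fit <- stats::.lm.fit(basis, values)
  sse <- sum(fit$residuals^2)
  n <- length(values)
  cf <- fit$coefficients
  names(cf) <- colnames(basis)
  structure(list(coefficients = cf, max_order = max_order, sse = sse,
                 aic = n * log(max(sse, .Machine$double.xmin) / n) + 2 * K,
                 n = n),
            class = "sh_fit")
}

#' Evaluate a spherical-harmonic expansion
#'
#' @param fit An `sh_fit`, or a named coefficient vector with `max_order`
#'   supplied.
#' @param dirs n x 3 unit directions at which to evaluate.
#' @param max_order Required if `fit` is a bare coefficient vector.
#' @return Numeric vector of length n.
#' @export
sh_eval <- function(fit, dirs, max_order = NULL) {
  if (inherits(fit, "sh_fit")) {
    cf <- fit$coefficients
    max_order <- fit$max_order
  } else {
    cf <- fit
    if (is.null(max_order)) stop("max_order required for bare coefficients")
  }
  as.numeric(sh_basis(dirs, max_order) %*% cf)
}

#' Compare spherical-harmonic fit orders by SSE and AIC
#'
#' Fits each row of an ADC-profile matrix at every requested even order and
#' tabulates fit error and AIC distributions. Because the basis columns are
#' nested (l-major ascending), one order-max basis serves all orders.
#'
#' @param adc_matrix Profiles x directions matrix of ADC values.
#' @param dirs Direction matrix shared by all profiles.
#' @param orders Even orders to compare (default 2, 4, 6, 8).
#' @return Object of class `sh_order_comparison`: `summary` data.frame
#'   (order, n_coef, mean/median SSE and AIC), plus full `sse` and `aic`
#'   matrices (profiles x orders).
#' @export
compare_sh_orders <- function(adc_matrix, dirs, orders = c(2, 4, 6, 8)) {
  adc_matrix <- as.matrix(adc_matrix)
  kmax <- max(orders)
  if (ncol(adc_matrix) < sh_coef_count(kmax))
    stop(sprintf("at least %d directions required for order %d",
                 sh_coef_count(kmax), kmax))
  B <- sh_basis(dirs, kmax)
  np <- nrow(adc_matrix)
  sse <- matrix(NA_real_, np, length(orders),
                dimnames = list(NULL, paste0("order", orders)))
  aic <- sse
  n <- ncol(adc_matrix)
  for (oi in seq_along(orders)) {
    K <- sh_coef_count(orders[oi])
    Bo <- B[, seq_len(K), drop = FALSE]
    qrB <- qr(Bo)
    res <- qr.resid(qrB, t(adc_matrix))
    sse[, oi] <- colSums(res^2)
    aic[, oi] <- n * log(pmax(sse[, oi], .Machine$double.xmin) / n) + 2 * K
  }
  summary <- data.frame(
    order = orders, n_coef = vapply(orders, sh_coef_count, numeric(1)),
    mean_sse = colMeans(sse), median_sse = apply(sse, 2, stats::median),
    mean_aic = colMeans(aic), median_aic = apply(aic, 2, stats::median),
    row.names = NULL
  )
  structure(list(summary = summary, sse = sse, aic = aic),
            class = "sh_order_comparison")
}

#' @export
print.sh_order_comparison <- function(x, ...) {
  print(x$summary, ...)
  invisible(x)
}
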