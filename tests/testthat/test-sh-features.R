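# ADC computation, signal interpolation, spherical-harmonic fitting and the
# layer / depth-profile feature vectors.

dirs60 <- make_gradient_scheme(60)$bvecs[-(1:6), ]

test_that("ADC definition and clipping policy", {
  expect_equal(compute_adc(1, 1, 3000), 0, ignore_attr = TRUE)
  expect_equal(as.numeric(compute_adc(exp(-0.9), 1, 3000)), 3.0e-4)
  # signal above s0: flagged, clipped to ratio 1 (ADC 0)
  a <- compute_adc(c(1.2, 0.5), 1, 3000)
  expect_true(attr(a, "flagged")[1])
  expect_false(attr(a, "flagged")[2])
  expect_equal(as.numeric(a[1]), 0)
  expect_equal(attr(a, "flagged_fraction"), 0.5)
  expect_error(compute_adc(0.5, 0, 3000), "invalid reference")
  # no-clip policy yields NA for flagged samples
  expect_true(is.na(compute_adc(1.2, 1, 3000, clip = FALSE)[1]))
})

test_that("trilinear sampling interpolates exactly where it must", {
  sch <- make_gradient_scheme(6, n_b0 = 3)
  dat <- array(0, c(4, 4, 4, 9))
  dat[, , , 1:3] <- 1
  set.seed(2)
  for (m in 4:9) dat[, , , m] <- array(runif(64), c(4, 4, 4))
  dwi <- structure(list(data = dat, scheme = sch, voxel_size = 0.5),
                   class = "dwi_volume")
  # voxel centre: exact voxel value
  s <- sample_signal_at_locations(dwi, cbind(1 * 0.5, 2 * 0.5, 1 * 0.5))
  expect_equal(s$signal[1, ], dat[2, 3, 2, 4:9])
  # midway between two voxels along one axis: arithmetic mean
  s2 <- sample_signal_at_locations(dwi, cbind(0.5 * 0.5, 0, 0))
  expect_equal(s2$signal[1, ], (dat[1, 1, 1, 4:9] + dat[2, 1, 1, 4:9]) / 2)
  # constant image: the constant anywhere
  s3 <- sample_signal_at_locations(dwi, cbind(0.33, 0.71, 0.29))
  expect_equal(s3$s0, 1)
  # out-of-bounds: excluded with warning
  expect_warning(
    s4 <- sample_signal_at_locations(dwi, rbind(c(0.2, 0.2, 0.2),
                                                c(9, 9, 9))),
    "out of volume")
  expect_equal(s4$kept, 1L)
})

test_that("even-SH coefficient counts and fit behaviour", {
  expect_equal(sh_coef_count(6), 28)
  expect_equal(sh_coef_count(8), 45)
  expect_equal(vapply(c(0, 2, 4), sh_coef_count, numeric(1)), c(1, 6, 15))
  # isotropic profile: l = 0 reproduces the constant, higher orders vanish
  fit <- fit_even_sh(rep(2.5e-4, 60), dirs60, 6)
  expect_lt(max(abs(fit$coefficients[-1])), 1e-10)
  expect_equal(sh_eval(fit, rbind(c(0, 0, 1), c(1, 0, 0))),
               rep(2.5e-4, 2))
  # nested least squares: SSE non-increasing with order
  set.seed(4)
  adc <- 2e-4 + 1e-4 * dirs60[, 3]^2 + rnorm(60, 0, 1e-5)
  sses <- vapply(c(2, 4, 6, 8), function(o)
    fit_even_sh(adc, dirs60, o)$sse, numeric(1))
  expect_true(all(diff(sses) <= 1e-18))
  # underdetermined fit is a rank error
  expect_error(fit_even_sh(rep(1, 20), dirs60[1:20, ], 6), "rank error")
})

test_that("least-squares projection leaves residuals orthogonal to the basis", {
  set.seed(5)
  adc <- 2e-4 + 5e-5 * dirs60[, 1]^2 + rnorm(60, 0, 2e-5)
  B <- sh_basis(dirs60, 6)
  fit <- fit_even_sh(adc, dirs60, 6, basis = B)
  resid <- adc - as.numeric(B %*% fit$coefficients)
  expect_lt(max(abs(crossprod(B, resid))), 1e-8)
})

test_that("order comparison favours parsimony via AIC", {
  # 90 directions: enough that the 45-coefficient order-8 fit is not in the
  # K ~ n regime where ln(SSE) fluctuations swamp the AIC penalty
  dirs90 <- make_gradient_scheme(90)$bvecs[-(1:6), ]
  set.seed(6)
  D <- diag(c(1e-4, 1e-4, 4e-4))
  adc <- rowSums((dirs90 %*% D) * dirs90) # single tensor: exactly order 2
  profs <- t(replicate(30, adc + rnorm(90, 0, 2e-6)))
  cmp <- compare_sh_orders(profs, dirs90)
  expect_equal(cmp$summary$n_coef, c(6, 15, 28, 45))
  expect_true(all(diff(colMeans(cmp$sse)) <= 0)) # SSE decreases with order
  # AIC minimum is not at order 8 (penalty dominates)
  expect_true(which.min(cmp$summary$mean_aic) != 4)
  # pure-noise profiles: SSE still decreases, AIC increases beyond the
  # generating complexity
  noise <- matrix(rnorm(30 * 90, 3e-4, 2e-5), 30, 90)
  cmpn <- compare_sh_orders(noise, dirs90)
  expect_true(all(diff(cmpn$summary$mean_sse) <= 0))
  expect_true(all(diff(cmpn$summary$mean_aic) > 0))
})

test_that("rotation to the cortical frame is minimal and consistent", {
  # normal already +z: identity
  expect_equal(rotate_to_cortical_frame(dirs60, c(0, 0, 1)), dirs60,
               ignore_attr = TRUE)
  # normal -z: a 180-degree tangential flip; even features are invariant
  d2 <- rotate_to_cortical_frame(dirs60, c(0, 0, -1))
  expect_equal(abs(d2[, 3]), abs(dirs60[, 3]))
  # generic normal maps onto +z
  n <- c(1, 2, 3) / sqrt(14)
  R <- rotation_to_z(n)
  expect_equal(as.numeric(R %*% n), c(0, 0, 1))
  expect_equal(det(R), 1)
  expect_error(rotation_to_z(c(0, 0, 0)), "zero normal")
})

test_that("layer features: isotropy, length and tangential dominance", {
  fit_iso <- fit_even_sh(rep(3e-4, 60), dirs60, 6)
  f <- extract_layer_features(fit_iso)
  expect_length(f, 31)
  expect_equal(unname(f[1:3]), rep(3e-4, 3))
  # isotropic profile: all 31 features invariant under rotation
  dirs_rot <- rotate_to_cortical_frame(dirs60, c(1, 1, 1) / sqrt(3))
  f2 <- extract_layer_features(fit_even_sh(rep(3e-4, 60), dirs_rot, 6))
  expect_equal(f, f2, tolerance = 1e-9)
  # tangential bi-tensor layer in the local frame: tangential > radial
  cfg <- tiny_config()
  ls <- cfg$layer_spec[cfg$layer_spec$name == "L1", ]
  sig <- cortlam:::bitensor_signal(dirs60[, 3]^2, cfg$b_value,
                                   ls$radial_fraction, ls$rad_axial,
                                   ls$rad_perp, ls$tan_inplane, ls$tan_normal)
  ft <- extract_layer_features(fit_even_sh(-log(sig) / cfg$b_value,
                                           dirs60, 6))
  expect_gt(ft["tangential"], ft["radial"])
  # the two equatorial-mean backends agree
  fit <- fit_even_sh(-log(sig) / cfg$b_value, dirs60, 6)
  expect_equal(cortlam:::sh_equatorial_mean(fit$coefficients, 6, "quadrature"),
               cortlam:::sh_equatorial_mean(fit$coefficients, 6, "analytic"),
               tolerance = 1e-8)
})

test_that("features are invariant to in-plane rotation and sign flips", {
  set.seed(8)
  worst <- 0
  for (rep in 1:50) {
    adc <- 2e-4 + 1e-4 * runif(1) * dirs60[, 3]^2 +
      5e-5 * runif(1) * dirs60[, 1]^2 + rnorm(60, 0, 1e-5)
    phi <- runif(1, 0, 2 * pi)
    Rz <- matrix(c(cos(phi), -sin(phi), 0, sin(phi), cos(phi), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    f1 <- extract_layer_features(fit_even_sh(adc, dirs60, 6))
    f2 <- extract_layer_features(fit_even_sh(adc, dirs60 %*% t(Rz), 6))
    # total/radial/tangential summaries are in-plane rotation invariant
    rel <- abs(f2[1:3] - f1[1:3]) / pmax(abs(f1[1:3]), 1e-12)
    worst <- max(worst, rel)
    # even basis: direction sign flips change nothing at all
    f3 <- extract_layer_features(fit_even_sh(adc, -dirs60, 6))
    expect_equal(f3, f1, tolerance = 1e-10)
  }
  expect_lt(worst, 1e-6)
})

test_that("depth-profile moments follow the central-moment definitions", {
  m <- depth_profile_moments(cbind(rep(2e-4, 9), rep(3e-4, 9), rep(1e-4, 9)))
  expect_length(m, 12)
  expect_equal(unname(m), c(2e-4, 0, 0, 0, 3e-4, 0, 0, 0, 1e-4, 0, 0, 0))
  m2 <- depth_profile_moments(cbind(1:9, 1:9, 1:9))
  expect_equal(unname(m2[1:4]), c(5, 20 / 3,
                                  mean((1:9 - 5)^3), mean((1:9 - 5)^4)))
  expect_true(all(m2[c(2, 4, 6, 8, 10, 12)] >= 0))
  expect_error(depth_profile_moments(cbind(c(1:8, NA), 1:9, 1:9)),
               "incomplete")
})

test_that("batch feature matrix agrees with the single-location path", {
  ph <- tiny_phantom()
  fx <- tiny_features()
  expect_equal(ncol(fx$feats), 31)
  i <- c(1, 11, 101)
  samp <- fx$samp
  sig <- sample_signal_at_locations(ph$dwi,
                                    cbind(samp$x[i], samp$y[i], samp$z[i]))
  for (q in seq_along(i)) {
    adc <- compute_adc(sig$signal[q, ], sig$s0[q], sig$b)
    dloc <- rotate_to_cortical_frame(sig$dirs,
                                     c(samp$nx[i[q]], samp$ny[i[q]],
                                       samp$nz[i[q]]))
    f <- extract_layer_features(fit_even_sh(as.numeric(adc), dloc, 6))
    expect_equal(unname(fx$feats[i[q], ]), unname(f), tolerance = 1e-10)
  }
})
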