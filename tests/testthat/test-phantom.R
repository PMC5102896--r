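# Phantom geometry, bi-tensor signal and Rician noise.

test_that("relative depth and layer placement follow the analytic geometry", {
  cfg <- tiny_config()
  tr <- tiny_phantom()$truth
  # a point at mid radius has relative depth 0.5 at any angle
  r_mid <- (cfg$inner_radius + cfg$outer_radius) / 2
  pts <- cbind(cfg$center_xy[1] + r_mid * cos(c(0.3, 1.2, 2.6)),
               cfg$center_xy[2] + r_mid * sin(c(0.3, 1.2, 2.6)), 1.0)
  lab <- cortlam:::phantom_labels_at(pts, cfg)
  expect_equal(lab$depth, rep(0.5, 3))
  # L1 (most superficial layer) voxels hug the pial shell
  d <- dim(tr$layer_labels)
  l1 <- which(tr$layer_labels == 4L)
  co <- (arrayInd(l1, d) - 1) * cfg$voxel_size
  r <- sqrt((co[, 1] - cfg$center_xy[1])^2 + (co[, 2] - cfg$center_xy[2])^2)
  shell <- 0.1 * (cfg$outer_radius - cfg$inner_radius)
  expect_true(all(r >= cfg$outer_radius - shell - cfg$voxel_size))
})

test_that("GM voxel count matches an independent radius scan", {
  cfg <- tiny_config()
  tr <- tiny_phantom()$truth
  d <- cfg$volume_shape
  co <- arrayInd(seq_len(prod(d)), d)
  pts <- (co - 1) * cfg$voxel_size
  dx <- pts[, 1] - cfg$center_xy[1]
  dy <- pts[, 2] - cfg$center_xy[2]
  r <- sqrt(dx^2 + dy^2)
  inside <- r >= cfg$inner_radius & r < cfg$outer_radius & dy >= 0
  expect_equal(sum(tr$gm_mask), sum(inside))
  # masks tile the volume and are mutually exclusive
  total <- tr$gm_mask + tr$wm_mask + tr$background_mask
  expect_true(all(total == 1))
  expect_equal(tr$gm_mask, tr$layer_labels > 0)
})

test_that("radial direction field is unit length on tissue", {
  tr <- tiny_phantom()$truth
  n2 <- tr$radial_direction[, , , 1]^2 + tr$radial_direction[, , , 2]^2 +
    tr$radial_direction[, , , 3]^2
  expect_true(all(abs(n2[tr$gm_mask] - 1) < 1e-12))
})

test_that("bi-tensor signal obeys its analytic limits", {
  cfg <- tiny_config()
  ph <- tiny_phantom()
  # b = 0 volumes carry S0 exactly
  b0 <- ph$clean$data[, , , 1:cfg$n_b0]
  expect_true(all(b0 == 1))
  # isotropic limit: f = 1 with equal diffusivities gives exp(-b d) everywhere
  d <- 3e-4
  s <- cortlam:::bitensor_signal(runif(20), cfg$b_value, 1, d, d, 0, 0)
  expect_equal(s, rep(exp(-cfg$b_value * d), 20))
  # tangentially dominated layer: radial ADC < mean equatorial ADC
  ls <- cfg$layer_spec[cfg$layer_spec$name == "L4", ]
  adc_of <- function(c2) -log(cortlam:::bitensor_signal(
    c2, cfg$b_value, ls$radial_fraction, ls$rad_axial, ls$rad_perp,
    ls$tan_inplane, ls$tan_normal)) / cfg$b_value
  radial_adc <- adc_of(1)                       # along the normal
  equatorial <- mean(adc_of(rep(0, 36)))        # tangential plane
  expect_lt(radial_adc, equatorial)
})

test_that("noise-free layer ADC ordering matches the configured ordering", {
  cfg <- tiny_config()
  ph <- tiny_phantom()
  # analytic oracle: spherical-mean ADC per layer from the configuration
  ana <- vapply(seq_len(nrow(cfg$layer_spec)), function(l)
    cortlam:::layer_mean_adc(cfg$layer_spec[l, ], cfg$b_value), numeric(1))
  # measured: mean ADC over directions in noise-free voxels of each layer
  dwi_i <- cortlam:::dwi_indices(ph$scheme)
  lay <- as.vector(ph$truth$layer_labels)
  meas <- vapply(seq_len(nrow(cfg$layer_spec)), function(l) {
    v <- which(lay == l)[1:50]
    sig <- t(vapply(v, function(ix) {
      co <- arrayInd(ix, dim(ph$truth$layer_labels))
      ph$clean$data[co[1], co[2], co[3], dwi_i]
    }, numeric(length(dwi_i))))
    mean(-log(sig) / cfg$b_value)
  }, numeric(1))
  expect_identical(order(ana), order(meas))
  expect_equal(meas, ana, tolerance = 0.02)
})

test_that("Rician noise has the expected statistics and determinism", {
  cfg <- tiny_config()
  ph <- tiny_phantom()
  # determinism: same seed, same realisation; truth labels are noise-free
  n1 <- add_rician_noise(ph$clean, 30, seed = 5)
  n2 <- add_rician_noise(ph$clean, 30, seed = 5)
  expect_identical(n1$data, n2$data)
  # sigma -> 0 limit: output equals input
  n0 <- add_rician_noise(ph$clean, 1e12, seed = 5)
  expect_equal(n0$data, ph$clean$data, tolerance = 1e-9)
  # zero true signal: Rayleigh mean sigma * sqrt(pi/2)
  zero <- ph$clean
  zero$data[, , , 7] <- 0 # one diffusion volume zeroed
  nz <- add_rician_noise(zero, 30, seed = 9)
  sigma <- attr(nz, "sigma")
  expect_equal(mean(nz$data[, , , 7]), sigma * sqrt(pi / 2),
               tolerance = 0.02)
})

test_that("measured b0 SNR honours the target", {
  # Monte-Carlo with enough b0 repetitions that the per-voxel mean/SD
  # estimator's small-sample bias is negligible: within 10% of the target.
  scheme <- make_gradient_scheme(6, n_b0 = 50)
  clean <- structure(list(data = array(1, c(20, 20, 5, 56)), scheme = scheme,
                          voxel_size = 0.34), class = "dwi_volume")
  noisy <- add_rician_noise(clean, 30, seed = 21)
  snr <- measure_snr(noisy$data[, , , 1:50])
  expect_lt(abs(snr$mean - 30), 3)
  # with only 6 repetitions (the acquisition design) the estimator runs high
  # (SD underestimation, ~+19% for n = 6) but stays in a plausible band
  ph <- tiny_phantom()
  b0 <- ph$dwi$data[, , , cortlam:::b0_indices(ph$scheme)]
  snr6 <- measure_snr(b0, mask = ph$truth$gm_mask)
  expect_gt(snr6$mean, 25)
  expect_lt(snr6$mean, 45)
})

test_that("noise realisation does not alter ground-truth labels", {
  cfg <- tiny_config()
  t1 <- build_geometry(cfg)
  t2 <- build_geometry(cfg)
  expect_identical(t1$layer_labels, t2$layer_labels)
})

test_that("geometry that exceeds the volume is rejected", {
  expect_error(phantom_config(volume_shape = c(24, 24, 8)),
               "exceeds volume bounds")
  expect_error(phantom_config(inner_radius = 9, outer_radius = 6), "smaller")
})
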