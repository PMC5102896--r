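# Shared fixtures, built in code and memoised per test run. The small
# phantom keeps unit tests fast; the acceptance tests build the full-size
# phantom themselves.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_config <- function() {
  phantom_config(volume_shape = c(56L, 56L, 10L), inner_radius = 5,
                 outer_radius = 8, snr = 30, seed = 7L)
}

tiny_phantom <- function() memo("tiny_phantom", generate_phantom(tiny_config()))

tiny_field <- function() memo("tiny_field", {
  tr <- tiny_phantom()$truth
  solve_laplace(tr$gm_mask, tr$wm_mask, tr$pial_mask,
                voxel_size = tiny_config()$voxel_size)
})

tiny_sampling <- function() memo("tiny_sampling", {
  cfg <- tiny_config()
  seeds <- phantom_grid_seeds(cfg, n_lm = 4L, n_ap = 30L)
  seed_mat <- cbind(as.vector(seeds[, , 1]), as.vector(seeds[, , 2]),
                    as.vector(seeds[, , 3]))
  prof <- trace_streamlines(tiny_field(), seed_mat)
  samp <- sample_depth_levels(prof, tiny_field())
  list(seeds = seeds, profiles = prof, samp = samp)
})

# 31-feature matrix plus analytic true labels on the noisy tiny phantom.
tiny_features <- function() memo("tiny_features", {
  ph <- tiny_phantom()
  samp <- tiny_sampling()$samp
  sig <- sample_signal_at_locations(ph$dwi, cbind(samp$x, samp$y, samp$z))
  samp <- samp[seq_len(nrow(samp)) %in% sig$kept, , drop = FALSE]
  feats <- layer_feature_matrix(sig$signal, sig$s0, sig$dirs, sig$b,
                                as.matrix(samp[, c("nx", "ny", "nz")]))
  true_layer <- cortlam:::phantom_labels_at(cbind(samp$x, samp$y, samp$z),
                                            ph$config)$layer
  list(feats = feats, samp = samp, true_layer = true_layer)
})

# Full-annulus masks (closed ribbon, no cut faces) for solver benchmarks.
full_annulus_masks <- function(a = 8, b = 11, shape = c(76, 76, 4),
                               voxel_size = 0.34) {
  ctr <- (shape[1:2] - 1) * voxel_size / 2
  ii <- (seq_len(shape[1]) - 1) * voxel_size - ctr[1]
  jj <- (seq_len(shape[2]) - 1) * voxel_size - ctr[2]
  r2 <- outer(ii^2, jj^2, "+")
  r <- sqrt(r2)
  gm2 <- r >= a & r < b
  wm2 <- r < a
  pial2 <- r >= b
  rep3 <- function(m) array(m, dim = shape)
  list(gm = rep3(gm2), wm = rep3(wm2), pial = rep3(pial2),
       r = rep3(r), a = a, b = b, voxel_size = voxel_size,
       center = ctr)
}

# Analytic Dirichlet data for the annulus benchmark (log potential evaluated
# at every voxel centre).
annulus_boundary_values <- function(masks) {
  array(log(pmax(masks$r, 1e-9) / masks$a) / log(masks$b / masks$a),
        dim = dim(masks$r))
}
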