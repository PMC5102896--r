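# Synthetic laminar cortical phantom: a half-annulus cortical ribbon extruded
# along z (a gyrus-like fold with analytic depth and surface normals), a
# depth-ordered set of layer-complexes with radially or tangentially dominated
# bi-tensor diffusion, an angular area border, single-shell HARDI signal at
# b = 3000 s/mm^2 and Rician magnitude noise.

#' Default layer-complex specification
#'
#' Four depth-ordered layer-complexes mimicking the laminar organisation seen
#' in motor/premotor cortex: a deep radial high-anisotropy complex (layers
#' 5/6), a thin tangential band (layer 4, present only in area B), a radial
#' low-anisotropy complex (layers 2/3) and a thin superficial tangential band
#' (layer 1). Depth 0 is the white/gray-matter boundary, depth 1 the pial
#' surface. Diffusivities are in mm^2/s in the fixed-tissue (ex vivo) regime
#' and additionally encode the depthwise decrease of total diffusivity from
#' the pial surface toward white matter that is characteristic of cortical
#' gray matter, so that the supragranular zone (layers 1-3) carries
#' systematically higher diffusivities than the infragranular zone.
#'
#' Each compartment is axially symmetric about the local radial direction:
#' the "radial" compartment is prolate along the normal
#' (\code{rad_axial > rad_perp}) and the "tangential" compartment oblate in
#' the tangential plane (\code{tan_inplane > tan_normal});
#' \code{radial_fraction} mixes the two.
#'
#' @return A data.frame with one row per layer-complex, deepest first.
#' @export
default_layer_spec <- function() {
  data.frame(
    name = c("L56", "L4", "L23", "L1"),
    depth_min = c(0.00, 0.35, 0.50, 0.90),
    depth_max = c(0.35, 0.50, 0.90, 1.00),
    radial_fraction = c(0.80, 0.30, 0.65, 0.25),
    rad_axial = c(3.6e-4, 2.8e-4, 5.2e-4, 4.2e-4),
    rad_perp = c(0.9e-4, 1.0e-4, 1.6e-4, 1.7e-4),
    tan_inplane = c(2.6e-4, 3.3e-4, 4.2e-4, 5.2e-4),
    tan_normal = c(0.9e-4, 1.0e-4, 1.6e-4, 1.7e-4),
    area_b_only = c(FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Phantom configuration
#'
#' Assembles and validates the configuration of the synthetic laminar
#' phantom. Defaults emulate a 340 um isotropic ex vivo acquisition with 60
#' diffusion directions at b = 3000 s/mm^2, six b0 volumes and b0 SNR 30.
#'
#' @param volume_shape Voxel counts per axis (length 3).
#' @param voxel_size Isotropic voxel size in mm.
#' @param inner_radius,outer_radius Annulus radii of the cortical ribbon (mm):
#'   the white/gray-matter boundary sits at `inner_radius`, the pial surface
#'   at `outer_radius`.
#' @param layer_spec Layer-complex table, see [default_layer_spec()].
#' @param area_split_angle Angular position (radians, in (0, pi)) of the
#'   border between area A (angle < split) and area B.
#' @param layer4_in_area_b_only If TRUE, layers flagged `area_b_only` are
#'   absent in area A and their depth range is absorbed by the layer below.
#' @param b_value,n_directions,n_b0 Acquisition parameters.
#' @param snr Target b0 signal-to-noise ratio (mean GM b0 / noise sigma).
#' @param wm_diffusivities Axial/perpendicular diffusivities (mm^2/s) of the
#'   white-matter tensor (radially oriented, fibres entering the cortex).
#' @param fluid_diffusivity Isotropic diffusivity of the embedding fluid.
#' @param center_xy Annulus centre in world mm; defaults to the mid x extent
#'   and 3 voxels up in y so the ribbon fits with margin.
#' @param seed Default seed used by [generate_phantom()] for noise.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(volume_shape = c(64L, 64L, 32L),
                           voxel_size = 0.34,
                           inner_radius = 6.0,
                           outer_radius = 9.0,
                           layer_spec = default_layer_spec(),
                           area_split_angle = pi / 2,
                           layer4_in_area_b_only = TRUE,
                           b_value = 3000,
                           n_directions = 60L,
                           n_b0 = 6L,
                           snr = 30,
                           wm_diffusivities = c(6.0e-4, 1.0e-4),
                           fluid_diffusivity = 2.0e-3,
                           center_xy = NULL,
                           seed = 1L) {
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 4L))
  if (inner_radius >= outer_radius)
    stop("inner_radius must be smaller than outer_radius")
  ls <- layer_spec
  ord <- order(ls$depth_min)
  ls <- ls[ord, , drop = FALSE]
  if (abs(ls$depth_min[1]) > 1e-12 || abs(ls$depth_max[nrow(ls)] - 1) > 1e-12)
    stop("layer depth ranges must tile [0, 1]")
  if (nrow(ls) > 1 &&
      any(abs(ls$depth_min[-1] - ls$depth_max[-nrow(ls)]) > 1e-12))
    stop("layer depth ranges must tile [0, 1] without gaps or overlap")
  dcols <- c("rad_axial", "rad_perp", "tan_inplane", "tan_normal")
  dvals <- unlist(ls[dcols])
  if (any(dvals <= 0) || any(dvals >= 3.0e-3))
    stop("layer diffusivities must lie in (0, 3.0e-3) mm^2/s")
  if (any(ls$radial_fraction < 0 | ls$radial_fraction > 1))
    stop("radial_fraction must lie in [0, 1]")
  if (is.null(center_xy)) {
    center_xy <- c((volume_shape[1] - 1) * voxel_size / 2, 3 * voxel_size)
  }
  extent <- (volume_shape - 1) * voxel_size
  if (center_xy[1] - outer_radius < 0 ||
      center_xy[1] + outer_radius > extent[1] ||
      center_xy[2] + outer_radius > extent[2])
    stop("geometry error: ribbon exceeds volume bounds")
  if (area_split_angle <= 0 || area_split_angle >= pi)
    stop("area_split_angle must lie in (0, pi)")
  structure(list(
    volume_shape = as.integer(volume_shape), voxel_size = voxel_size,
    inner_radius = inner_radius, outer_radius = outer_radius,
    layer_spec = ls, area_split_angle = area_split_angle,
    layer4_in_area_b_only = layer4_in_area_b_only,
    b_value = b_value, n_directions = as.integer(n_directions),
    n_b0 = as.integer(n_b0), snr = snr,
    wm_diffusivities = wm_diffusivities,
    fluid_diffusivity = fluid_diffusivity,
    center_xy = center_xy, seed = as.integer(seed)
  ), class = "phantom_config")
}

# Cylindrical coordinates of world points relative to the annulus centre.
#' @keywords internal
phantom_polar <- function(pts, config) {
  dx <- pts[, 1] - config$center_xy[1]
  dy <- pts[, 2] - config$center_xy[2]
  list(r = sqrt(dx^2 + dy^2), theta = atan2(dy, dx))
}

# Ground-truth layer/area labels at arbitrary world points (analytic oracle).
# Returns 0 outside the ribbon.
#' @keywords internal
phantom_labels_at <- function(pts, config) {
  pol <- phantom_polar(pts, config)
  depth <- (pol$r - config$inner_radius) /
    (config$outer_radius - config$inner_radius)
  in_gm <- depth >= 0 & depth < 1 & pol$theta >= 0 & pol$theta <= pi
  area <- ifelse(pol$theta < config$area_split_angle, 1L, 2L)
  area[!in_gm] <- 0L
  ls <- config$layer_spec
  layer <- rep(0L, nrow(pts))
  idx <- findInterval(pmin(pmax(depth, 0), 1 - 1e-12), ls$depth_min)
  idx[!in_gm] <- NA
  if (config$layer4_in_area_b_only && any(ls$area_b_only)) {
    absent <- !is.na(idx) & ls$area_b_only[idx] & area == 1L
    idx[absent] <- pmax(idx[absent] - 1L, 1L)
  }
  layer[in_gm] <- idx[in_gm]
  list(layer = layer, area = area, depth = depth, r = pol$r,
       theta = pol$theta)
}

#' Build the phantom geometry and ground truth
#'
#' Voxelises the half-annulus ribbon: gray matter between the inner and outer
#' radii in the upper half-plane, white matter inside the inner radius,
#' embedding fluid elsewhere. Layer labels follow the analytic relative depth
#' (radial fraction between the two radii) against the layer specification;
#' area labels follow the angular position against the split angle.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_truth`: integer volumes
#'   `layer_labels` (0 = non-cortex, 1..L deepest to most superficial) and
#'   `area_labels`, binary `wm_mask`, `gm_mask`, `background_mask` and
#'   `pial_mask` (fluid beyond the pial surface, used as the outer Dirichlet
#'   boundary), and `radial_direction` (unit outward normals, dim = c(shape, 3),
#'   defined on GM and WM).
#' @export
build_geometry <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$volume_shape
  vs <- config$voxel_size
  ctr <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  pts <- cbind((ctr$i - 1) * vs, (ctr$j - 1) * vs, (ctr$k - 1) * vs)
  lab <- phantom_labels_at(pts, config)

  upper <- lab$theta >= 0 & lab$theta <= pi
  gm <- lab$layer > 0L
  wm <- upper & lab$r < config$inner_radius
  pial <- upper & lab$r >= config$outer_radius
  bg <- !gm & !wm

  shp <- function(v) array(v, dim = d)
  nrm <- cbind(cos(lab$theta), sin(lab$theta), 0)
  nrm[!(gm | wm), ] <- 0
  radial <- array(0, dim = c(d, 3L))
  radial[, , , 1] <- shp(nrm[, 1])
  radial[, , , 2] <- shp(nrm[, 2])

  structure(list(
    layer_labels = shp(as.integer(lab$layer)),
    area_labels = shp(as.integer(ifelse(gm, lab$area, 0L))),
    wm_mask = shp(wm), gm_mask = shp(gm),
    background_mask = shp(bg), pial_mask = shp(pial & bg),
    radial_direction = radial,
    voxel_size = vs, config = config
  ), class = "phantom_truth")
}

# Per-direction normalised bi-tensor signal for axisymmetric compartments:
# both compartments share the symmetry axis n, so the signal depends on the
# direction only through c2 = (g . n)^2.
#' @keywords internal
bitensor_signal <- function(c2, b, f, rad_axial, rad_perp, tan_inplane,
                            tan_normal) {
  f * exp(-b * (rad_perp + (rad_axial - rad_perp) * c2)) +
    (1 - f) * exp(-b * (tan_inplane + (tan_normal - tan_inplane) * c2))
}

# Analytic spherical-mean ADC of a layer's bi-tensor profile at a given
# b-value (numerical quadrature over the sphere); used as an independent
# oracle for layer ordering checks.
#' @keywords internal
layer_mean_adc <- function(layer_row, b, n_quad = 5000) {
  dirs <- spherical_fibonacci(n_quad)
  c2 <- dirs[, 3]^2 # symmetry axis can be taken as z
  s <- bitensor_signal(c2, b, layer_row$radial_fraction, layer_row$rad_axial,
                       layer_row$rad_perp, layer_row$tan_inplane,
                       layer_row$tan_normal)
  mean(-log(s) / b)
}

#' Simulate the noise-free diffusion-weighted signal
#'
#' Per gray-matter voxel the normalised signal is a two-compartment mixture
#' S(g)/S0 = f exp(-b g'D_rad g) + (1-f) exp(-b g'D_tan g) with D_rad prolate
#' along the local radial direction and D_tan oblate in the tangential plane,
#' parameters taken from the voxel's layer. White matter uses a single
#' radially oriented tensor; background uses isotropic free-fluid diffusion.
#' S0 = 1 everywhere.
#'
#' @param truth A [build_geometry()] result.
#' @param config The matching [phantom_config()].
#' @param scheme A [make_gradient_scheme()] result.
#' @return An object of class `dwi_volume`: list with `data` (4D array,
#'   volumes last), `scheme`, `voxel_size`.
#' @export
simulate_signal <- function(truth, config, scheme) {
  stopifnot(inherits(truth, "phantom_truth"),
            inherits(scheme, "gradient_scheme"))
  d <- config$volume_shape
  nvol <- length(scheme$bvals)
  dat <- array(1, dim = c(d, nvol)) # b0 signal: S0 = 1 exactly
  dwi <- dwi_indices(scheme)
  gdirs <- scheme$bvecs[dwi, , drop = FALSE]
  b <- config$b_value

  nx <- as.vector(truth$radial_direction[, , , 1])
  ny <- as.vector(truth$radial_direction[, , , 2])
  nz <- as.vector(truth$radial_direction[, , , 3])
  lay <- as.vector(truth$layer_labels)
  wm <- as.vector(truth$wm_mask)
  bg <- as.vector(truth$background_mask)

  sig <- matrix(NA_real_, length(lay), length(dwi))
  # background: isotropic fluid
  sig[bg, ] <- exp(-b * config$fluid_diffusivity)
  # white matter: single prolate tensor along the radial direction
  if (any(wm)) {
    c2 <- (cbind(nx[wm], ny[wm], nz[wm]) %*% t(gdirs))^2
    wmp <- config$wm_diffusivities
    sig[wm, ] <- bitensor_signal(c2, b, 1, wmp[1], wmp[2], 0, 0)
  }
  ls <- config$layer_spec
  for (l in seq_len(nrow(ls))) {
    v <- lay == l
    if (!any(v)) next
    c2 <- (cbind(nx[v], ny[v], nz[v]) %*% t(gdirs))^2
    sig[v, ] <- bitensor_signal(c2, b, ls$radial_fraction[l], ls$rad_axial[l],
                                ls$rad_perp[l], ls$tan_inplane[l],
                                ls$tan_normal[l])
  }
  if (anyNA(sig)) stop("config error: voxels without layer parameters")
  for (m in seq_along(dwi)) dat[, , , dwi[m]] <- array(sig[, m], dim = d)

  structure(list(data = dat, scheme = scheme, voxel_size = config$voxel_size),
            class = "dwi_volume")
}

#' Add Rician noise to a diffusion-weighted volume
#'
#' Each measurement m is replaced by sqrt((m + n1)^2 + n2^2) with n1, n2
#' independent zero-mean Gaussians of standard deviation
#' sigma = S0_reference / snr, the magnitude-MR noise model. The reference
#' S0 is the mean b0 signal over `mask` (all voxels if NULL).
#'
#' @param dwi A `dwi_volume`.
#' @param snr Target b0 signal-to-noise ratio (> 0).
#' @param seed Integer seed; fixed seed gives reproducible noise.
#' @param mask Optional logical volume over which the reference S0 is taken.
#' @return A `dwi_volume` with noisy data; attribute `sigma` records the
#'   noise level used.
#' @export
add_rician_noise <- function(dwi, snr, seed = NULL, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"), snr > 0)
  b0 <- b0_indices(dwi$scheme)
  if (length(b0) == 0) stop("no b0 volumes to reference noise level")
  d <- dim(dwi$data)
  b0dat <- dwi$data[, , , b0, drop = FALSE]
  s0_ref <- if (is.null(mask)) mean(b0dat) else
    mean(apply(b0dat, 4, function(v) mean(v[mask])))
  sigma <- s0_ref / snr
  if (!is.null(seed)) set.seed(seed)
  n <- length(dwi$data)
  noisy <- sqrt((dwi$data + stats::rnorm(n, 0, sigma))^2 +
                  stats::rnorm(n, 0, sigma)^2)
  out <- dwi
  out$data <- array(noisy, dim = d)
  attr(out, "sigma") <- sigma
  out
}

#' Generate a complete phantom dataset
#'
#' Convenience wrapper: geometry, gradient scheme, noise-free signal and a
#' Rician-noise realisation at the configured SNR.
#'
#' @param config A [phantom_config()].
#' @param noise_seed Seed for the noise realisation (defaults to
#'   `config$seed`).
#' @return List with `config`, `truth`, `scheme`, `clean` (noise-free
#'   `dwi_volume`) and `dwi` (noisy `dwi_volume`).
#' @export
generate_phantom <- function(config = phantom_config(), noise_seed = NULL) {
  if (is.null(noise_seed)) noise_seed <- config$seed
  truth <- build_geometry(config)
  scheme <- make_gradient_scheme(config$n_directions, config$n_b0,
                                 config$b_value)
  clean <- simulate_signal(truth, config, scheme)
  noisy <- add_rician_noise(clean, config$snr, seed = noise_seed,
                            mask = truth$gm_mask)
  list(config = config, truth = truth, scheme = scheme, clean = clean,
       dwi = noisy)
}
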