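# cortlam

Automatic, observer-independent segmentation of **cortical layer-complexes**
and **architectural area boundaries** from high-resolution diffusion MRI
(dMRI), with a synthetic laminar cortical phantom for end-to-end testing.

At very high spatial resolution (~340 µm) the diffusion signal in cortical
gray matter is sensitive to the radial and tangential organisation of
myelinated fibres, which differs between cortical layers and between
architectonic areas. `cortlam` turns a single-shell HARDI acquisition
(e.g. 60 directions at b = 3000 s/mm², plus b0 volumes) and tissue masks
into laminar segmentations, for researchers doing MR-based cortical
histology on ex vivo samples.

## Method

1. **Cortical depth** — solve the Laplace equation Δu = 0 across the
   gray-matter ribbon with u = 0 on the white/gray-matter boundary and u = 1
   at the pial boundary; integrate streamlines of ∇u and sample each profile
   at nine relative depths (10–90%, arc-length parameterisation).
2. **Features** — per direction, the apparent diffusion coefficient
   ADCᵢ = −(1/b) ln(Sᵢ/S₀); per location, a 6th-order *even* real
   spherical-harmonic (SH) fit of the ADC profile after rotating the local
   surface normal to the z-axis ("local cortical frame"). The layer feature
   vector is (total, radial, tangential diffusivity) + 28 SH coefficients =
   31 features. Fit order is justified by SSE/AIC comparison over orders
   2–8.
3. **Layer clustering** — squared-Euclidean k-means on the z-scored
   (locations × depths) × 31 matrix, best of 100 random restarts, with the
   number of clusters guided by the mean silhouette index
   s(i) = (b(i) − a(i))/max(a(i), b(i)) over k = 2..7; clusters are
   renumbered by mean cortical depth and can be mode-filter upsampled for
   display.
4. **Area boundaries** — a 100 × 200 × 9 grid of depth profiles is averaged
   latero-medially to 10 × 200 × 9; each profile is summarised by 12 moment
   features (mean and central moments m₂–m₄ of total/radial/tangential
   diffusivity over depth). Sliding blocks of N = 12..24 profiles are
   compared by the Mahalanobis distance D = (X̄₁−X̄₂)C⁻¹(X̄₁−X̄₂)′ with
   Hotelling's T² / Bonferroni significance; significant detections are
   counted over scales and rows and thresholded at mean + 4.5 SD.
5. **Validation** — contingency cross-tables with optimal class matching and
   χ² statistics, reference-label grouping and nearest-neighbour
   downsampling, matched-cluster profile correlations, b0 SNR measurement.

Because suitable ex vivo tissue data cannot be bundled, the `phantom` module
generates a folded cortical ribbon (half-annulus, analytic depths and
normals) with four depth-ordered layer-complexes of radially or tangentially
dominated bi-tensor diffusion, an area border at a configurable angle
(layer 4 present on one side only), and Rician noise at a target b0 SNR.

## Worked example

```r
library(cortlam)

cfg   <- phantom_config(volume_shape = c(64, 64, 16))  # 0.34 mm, SNR 30
ph    <- generate_phantom(cfg)
tr    <- ph$truth
field <- solve_laplace(tr$gm_mask, tr$wm_mask, tr$pial_mask,
                       voxel_size = cfg$voxel_size)

seeds <- phantom_grid_seeds(cfg, n_lm = 10, n_ap = 60)
prof  <- trace_streamlines(field, matrix(seeds, ncol = 3))
samp  <- sample_depth_levels(prof, field)
sig   <- sample_signal_at_locations(ph$dwi, cbind(samp$x, samp$y, samp$z))
feats <- layer_feature_matrix(sig$signal, sig$s0, sig$dirs, sig$b,
                              as.matrix(samp[, c("nx", "ny", "nz")]))

k2 <- order_clusters_by_depth(
  kmeans_best_of(feats, 2, n_restarts = 100, seed = 11), samp$level)
print(k2)
#> k-means result: k = 2, n = 5400, objective = 1.487e+05 (best of 100 restarts)

truth <- cortlam:::phantom_labels_at(cbind(samp$x, samp$y, samp$z), cfg)
cross_table(cortlam:::merge_truth_two_zones(truth$layer, cfg), k2$labels)
#> cross-table: n = 5400, mean matched fraction = 0.956, chi2 = 4490 (dof 1, p = 0)
#>    b
#> a      1    2
#>   1 2572  128
#>   2  110 2590
```

The matched fraction is the proportion of locations of each true
compartment (here: infragranular vs supragranular) assigned to its matched
cluster — 0.95+ means the unsupervised clustering recovers the laminar
zones almost perfectly at SNR 30. Area boundaries:

```r
gseeds <- phantom_grid_seeds(cfg, n_lm = 30, n_ap = 100)
grid   <- build_grid(field, ph$dwi, gseeds)
detect_area_boundaries(grid, lm_block = 10)
#> boundary detection: threshold 20.75 (mean + 4.5 SD)
#> boundaries at antero-posterior positions: 51
```

Position 51 is exactly where the phantom's area border (layer 4 appearing)
crosses the antero-posterior grid axis.

A thin command-line driver covers the same stages
(`inst/cli/cortlam.R`): `phantom generate`, `depth sample`,
`features extract`, `layers cluster`, `areas detect`, `validate crosstab`,
`pipeline run`.

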