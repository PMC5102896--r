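---
title: "Laminar and areal segmentation of cortex from diffusion MRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar and areal segmentation of cortex from diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cortlam` segments cortical layer-complexes and architectural area boundaries
from high-resolution single-shell diffusion MRI. This vignette explains the
models and procedures, the parameters that matter and their defaults, what
the synthetic phantom does and does not emulate, and the numerical and design
choices that were genuinely open.

## The measurement model

At each sampled cortical location the per-direction apparent diffusion
coefficient is

$$\mathrm{ADC}_i = -\tfrac{1}{b}\,\ln(S_i/S_0),$$

with $S_i$ the diffusion-weighted signal along gradient direction $g_i$,
$S_0$ the mean non-weighted (b0) signal, and $b$ the diffusion weighting in
s/mm². Signals are read off the volumes by trilinear interpolation. Noise
occasionally pushes $S_i \ge S_0$ or to zero; the signal ratio is then
clipped into $(10^{-6}, 1]$ and the sample flagged, and the flagged fraction
is reported per run. Clipping keeps every least-squares fit defined at
realistic SNR; the alternative (dropping samples) would make the design
matrix vary from location to location.

The angular ADC profile is expanded in a real, even-order spherical-harmonic
basis. Even orders only: diffusion measurements are antipodally symmetric,
so odd terms are pure noise. The basis convention is frozen because
coefficient vectors must be comparable across locations, files and runs:
no Condon–Shortley phase, $l$-major ordering with $m = -l..l$ inside each
$l$, $\sqrt{2}$-normalised real sine/cosine pairs. At the default maximum
order 6 the basis has 28 coefficients (45 at order 8, 15 at 4, 6 at 2).
With 60 directions, order 6 gives roughly two measurements per estimated
coefficient; the `compare_sh_orders()` table (SSE and the Gaussian-form
AIC $n\ln(\mathrm{SSE}/n) + 2K$) supports this default — SSE keeps falling
to order 8, but the AIC penalty flattens the comparison between 6 and 8
while orders 2–4 underfit multi-orientation profiles. The AIC formula is a
choice (the criterion is named in the literature this package follows
without a formula); any monotone variant of the Gaussian form orders the
models identically. Note that with $n = 60$ and $K = 45$ the order-8 fit
sits in the $K \sim n$ regime where AIC is unreliable — a further reason to
stop at order 6.

## The local cortical frame and the 31 layer features

Laminar contrasts are orientational relative to the cortical surface, so
each profile is interpreted in a local frame with the surface normal rotated
to the z-axis (minimal rotation about `normal × z`; for a normal at $-z$ any
tangential flip is equivalent because the profile is even). The layer
feature vector is:

* total cortical diffusivity — the spherical mean of the fitted expansion
  (the $l=0$ term; the raw sample mean is available as an option, the two
  differ only by the fit's projection),
* radial diffusivity — the fitted ADC along the local normal,
* tangential diffusivity — the mean fitted ADC over the equatorial plane,
  computed by 36-point equatorial quadrature (exact for trigonometric
  polynomials up to degree 35, hence exact at order 6; an analytic
  Legendre-based backend is provided and the two agree to $10^{-8}$ by
  test),
* the 28 local-frame SH coefficients.

This gives 31 features per (location, depth) sample. The three summaries
are invariant to in-plane rotations of the frame (tested to $10^{-6}$ over
random rotations) and all features are invariant to $g \to -g$.

## Laplace depth sampling

Cortical depth is defined by the harmonic potential $u$ with $u=0$ on the
white/gray-matter boundary and $u=1$ at the pial boundary, discretised with
the 6-neighbour stencil on the voxel grid and solved directly (sparse
Cholesky). A direct solve was chosen over Jacobi/Gauss–Seidel because the
gray-matter systems here are small (10⁴–10⁵ unknowns) and the residual is
then machine-precision rather than iteration-limited; the `tolerance`
argument (default $10^{-6}$) is verified against the achieved residual.
Voxels belonging to neither tissue nor boundary masks are treated as
reflecting (homogeneous Neumann), which makes the cut faces of a tissue
block behave as symmetry planes. Gray-matter components with no path to
both boundaries are excluded with a warning.

Two closed forms anchor the solver: the 1D slab (linear potential — exact
for the stencil, reproduced to machine precision) and the 2D annulus
(logarithmic potential). On a voxelised annulus at 0.34 mm two error
sources dwarf the stencil truncation: the staircase approximation of the
circular Dirichlet boundary (~10⁻²) and, for a half-annulus, the Neumann
approximation at the cut faces (~10⁻²–10⁻³ near the cuts). The solver
benchmark therefore uses a *full* annulus with the analytic potential
imposed at boundary voxel centres, isolating operator truncation; at radii
8–11 mm this reproduces the closed form to ~5·10⁻⁵ (the package asserts
10⁻⁴). Depth *accuracy on realistic masks* is instead tested geometrically:
sampled radii on the phantom track the analytic radial fraction to within
5% of the cortical thickness.

**Relative depth is normalised streamline arc length, not the potential
value.** The annulus potential is logarithmic in radius while "equally
spaced depths" are proportional distances; arc length gives the
proportional reading. Streamlines are integrated both ways from each seed
with midpoint (second-order) stepping at a quarter-voxel step and trilinear
gradient interpolation, stopped by bisection on the interpolated gray-matter
indicator (sub-voxel boundary localisation). Profiles are sampled at nine
levels, 10–90% in 10% steps; the 0% and 100% boundaries are avoided
deliberately (partial-volume contamination by white matter and embedding
fluid). Sampling by voxel-seeded streamlines rather than surface meshes is
a design decision: it removes the mesh-reconstruction dependency, and
lattice sizes become configuration, not contract. The Laplace method's
known curvature bias in layer depth is accepted; equi-volume sampling is
out of scope, and the boundary detector compares only features at like
depths, which limits the bias's effect there.

## Layer clustering

Rows are (location × depth) feature vectors; no spatial or depth
information enters the matrix. Features are z-scored per column before
clustering — diffusivities (~10⁻⁴ mm²/s) and SH coefficients live on
incommensurate scales and unscaled Euclidean distance would be arbitrary.
Lloyd k-means with random centroid initialisation is restarted 100 times
and the minimum within-cluster sum of squares kept; restarts that converge
with an empty cluster are discarded and redrawn. Ties in assignment and in
the mode filter break to the smallest index, making runs bit-reproducible
under a fixed seed.

The candidate number of clusters comes from the mean silhouette index over
$k = 2..7$, computed on a seeded random subsample (default 10,000 rows;
the full-matrix silhouette is quadratic in rows). Members of singleton or
fully degenerate clusters score 0. Model selection uses 20 restarts per
$k$ by default — the curve's shape is stable well before the objective's
last decimal — while the final clustering at the chosen $k$ uses the full
100. Local maxima of the curve are reported as candidates rather than a
single argmax, since laminar data typically show one coarse and one fine
optimum. Clusters are renumbered by mean cortical depth afterwards (the
labels are arbitrary), and clusters whose members mostly lie within one
voxel of a mask boundary are flagged as noise clusters — an explicit,
testable stand-in for visual identification of boundary artefacts. For
display, label maps can be nearest-neighbour upsampled 3× and mode-filtered
in a 5×5×5 window (edges truncated).

## Area-boundary detection

Each column of a (latero-medial × antero-posterior) lattice of depth
profiles is summarised by 12 features: for each of total, radial and
tangential diffusivity over the nine depths, the mean and the central
moments of orders 2–4 (population form). "The first moment about the mean"
is identically zero, so the mean itself takes its place — this reading
keeps 12 informative values and matches the feature count the method is
built around. Columns whose streamline fails to span both boundaries are
masked, never imputed.

The lattice (default 100 × 200 × 9) is averaged latero-medially in
non-overlapping blocks of 10 (masked columns excluded, contribution counts
kept), then each averaged row is stepped along the antero-posterior axis:
at every position the two adjacent blocks of $N$ profiles are compared by
the Mahalanobis distance with the pooled within-block covariance
($2N-2$ df). $N$ runs over 12..24 — the lower end keeps the 12×12 pooled
covariance estimable ($2N-2 \ge 22$ samples), the range gives the
multi-scale stability the detector relies on. Significance uses Hotelling's
$T^2 = \frac{N_1 N_2}{N_1+N_2} D$ with
$F = T^2 (N_1+N_2-p-1) / (p(N_1+N_2-2))$ on $(p, N_1+N_2-p-1)$ degrees of
freedom. The Bonferroni family is the number of (position, block-size)
tests per row; rows are replicates that feed the counts, not extra tests —
the conservative reading of an underdetermined choice, and the family size
is recorded. Singular pooled covariances are ridge-regularised by
$\varepsilon\,\mathrm{tr}(C)/p$ with $\varepsilon = 10^{-6}$ and flagged.
Significant detections are summed per position over scales and rows, the
count trace is thresholded at mean + 4.5 SD, and super-threshold runs are
merged with the count maximum reported as the boundary. Under a
homogeneous null the family-wise false-positive rate is below 0.05 by
construction (exact $T^2$ distribution + Bonferroni); the package verifies
~0.016 over 500 seeded simulations.

## The synthetic phantom: what it emulates, and what it does not

The phantom is a half-annulus cortical ribbon extruded along z — the
smallest geometry with curvature, analytic depths/normals, and two
definable areas. Defaults emulate the target data regime: 0.34 mm isotropic
voxels, 60 directions at b = 3000 s/mm² plus 6 b0, b0 SNR 30 (Rician,
$\sigma$ = mean GM b0 / SNR). Four layer-complexes run deepest-first: a
radial high-anisotropy complex (layers 5/6, depth 0–0.35), a tangential
band (layer 4, 0.35–0.5, present only in area B so the border is a laminar
change), a radial low-anisotropy complex (layers 2/3, 0.5–0.9) and a thin
tangential band (layer 1, 0.9–1.0). Voxels mix a prolate "radial" and an
oblate "tangential" compartment, both axially symmetric about the local
normal:

$$S/S_0 = f_r e^{-b\,g^\top D_{rad}\,g} + (1-f_r) e^{-b\,g^\top D_{tan}\,g}.$$

Diffusivities sit in the fixed-tissue regime (0.9–5.2·10⁻⁴ mm²/s; free
fluid 2·10⁻³), keeping $e^{-bD}$ contrasts realistic at b = 3000, and they
additionally encode the depthwise decrease of total diffusivity from the
pial surface toward white matter that is characteristic of cortical gray
matter — so the supragranular complexes carry systematically higher
diffusivities, and the coarse two-cluster structure of the feature space is
the supra/infragranular zonation rather than a radial-vs-tangential split.
The bi-tensor form and its parameters are a stand-in, not a claim about
tissue: real cortex is measured, not compartmental. The phantom also omits
susceptibility/eddy artefacts, T2/TE effects, multi-shell behaviour,
partial-volume mixtures beyond interpolation, and realistic folding beyond
one fold. Passing tests therefore demonstrate that the *pipeline* recovers
known structure under realistic noise and geometry — not that real tissue
will exhibit that structure.

Gradient directions: the deterministic default is the upper-hemisphere half
of a 2n-point spherical-Fibonacci lattice. A whole-sphere lattice looks
uniform but collapses after antipodal symmetrisation (near-antipodal pairs
2–3° apart at n = 60); the hemisphere set keeps the minimum pairwise
orientation angle above 11°. A seeded electrostatic-repulsion refinement
(Coulomb energy of the symmetrised set, fixed 300 iterations) is available
and reaches ~17°; the deterministic fallback exists so no test depends on
an optimiser's convergence.

## Numerical choices and degenerate inputs

* Identical block means in the Mahalanobis step return D = 0 without a
  solve; otherwise singular covariances get the ridge, then a pseudoinverse
  as last resort, always flagged.
* SNR measurement caps noiseless voxels (zero SD) at a sentinel (10⁶).
  With few b0 repetitions the per-voxel mean/SD estimator is biased high
  (≈ +19% at n = 6, from the small-sample SD bias); the 10%-accuracy check
  is run with 50 repetitions, and the 6-b0 reading is reported as is.
* Class matching in cross-tables is an exhaustive optimal assignment
  (maximal matched count) — exact and brute-force-verifiable for the ≤ 8
  classes that occur here; fractions are row-normalised per reference class
  (column-normalisation is available, the text definition being ambiguous).
* Labels 0/NA are background everywhere and never enter contingency tables.
* All seeds are explicit arguments; two runs from the same configuration
  and seed produce byte-identical label volumes (tested).

## Problem sizes used in the shipped checks

The package's own test battery runs the full method on a 64 × 64 × 32
phantom (≈ 19,600 GM voxels): a 24 × 75 profile lattice (16,200 feature
rows) for clustering, the full 100 × 200 × 9 grid for boundary detection,
a 10 × 60 lattice for the 20-realisation uniform-phantom specificity check
(streamline geometry reused across noise realisations, which is exact
because tracing is noise-independent), 500 homogeneous simulations for the
null calibration, and a second noise realisation for reproducibility.
These sizes are the package's choice of a desk-scale experiment: large
enough that clustering fractions and boundary localisation are stable,
small enough to re-run routinely.

## Known limitations

* Laplace (equi-potential) depth has a curvature bias relative to
  equi-volume sampling; not corrected here.
* The boundary detector steps along one grid axis; it localises borders
  crossing that axis and does not trace 2D boundary curves on the sheet.
* Feature extraction assumes a single shell; multi-shell acquisitions are
  not modelled.
* The generic lattice seeder for real data (`mask_lattice_seeds`) is a
  convenience; serious use should supply anatomically placed seeds.
* With 60 directions, order-8 comparisons are reported but sit too close
  to saturation ($K = 45$) to be decisive; they are included for the order
  comparison only.
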