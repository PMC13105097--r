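---
title: "Quantifying white-matter fiber architecture with fiberarch"
author: "fiberarch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying white-matter fiber architecture with fiberarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberarch)
```

## The problem

High-resolution light microscopy of labeled axons (for example neurofilament
heavy chain, NFH, which marks large-caliber myelinated projection axons)
shows that white matter is not a homogeneous cable tract. At the scale of a
few hundred micrometers it organizes into distinct local motifs:

* a **multi-orientation meshwork** — sparse fibers pointing in many
  directions with no local bundling;
* a **laminar / orthogonal** arrangement — stacked slabs of parallel fibers
  whose direction alternates between two near-orthogonal axes with a
  well-defined spatial period;
* **bundles** — dense, nearly parallel fibers with a single dominant
  orientation.

`fiberarch` turns a 3D single-channel intensity volume (bright tubes on a
dark background, voxel size in micrometers) into quantitative per-region
summaries of this organization: orientation distribution functions (ODFs),
generalized fractional anisotropy (GFA), orientation peaks, correlation
lengths of the orientation field, and a binary laminar map. A synthetic
phantom generator with voxel-level ground truth closes the loop for
validation.

## Per-voxel orientations: the structure tensor

Fiber direction is estimated from local intensity gradients. With
derivative-of-Gaussian gradients at scale $\sigma_g$ and Gaussian window
$\sigma_w$, the structure tensor at voxel $x$ is

$$ T(x) \;=\; G_{\sigma_w} * \big(\nabla I \,\nabla I^{\mathsf T}\big)(x). $$

For a bright tubular structure, intensity varies least *along* the tube, so
the fiber axis is the eigenvector of the **smallest** eigenvalue
($\lambda_1 \le \lambda_2 \le \lambda_3$). Coherence is
$(\lambda_2-\lambda_1)/(\lambda_1+\lambda_2+\lambda_3)$ clipped to
$[0,1]$: zero for isotropic neighborhoods, large when one axis is clearly
least-varying. Energy is the tensor trace.

Choices that matter:

* **Scales.** Defaults are $\sigma_g = 1\,\mu m$ (one fiber radius) and
  $\sigma_w = 3\,\mu m$ (three radii), so the window integrates gradients
  across a full tube cross-section. Both are physical lengths converted to
  per-axis voxel sigmas, so anisotropic voxels are handled transparently.
* **Validity mask.** A voxel contributes downstream only if its energy
  reaches 10% of the volume-mean energy. Tube-edge gradients carry orders
  of magnitude more energy than detector-noise gradients, so this floor
  separates labeled tissue from background across the full noise range the
  phantoms emulate, while on dense tissue it keeps nearly every voxel. A
  floor relative to the *median* energy fails as soon as most voxels are
  background: the median then *is* the noise level and background
  orientations flood the ODFs.
* **Borders.** Voxels within $\lceil 3\sigma_w \rceil$ of the volume edge
  are invalid (filter support), anticipating the masking of border cubes in
  the spatial maps.
* **Axial convention.** Orientations are axial ($v \equiv -v$). Vectors are
  sign-canonicalized (largest-magnitude component positive, ties broken in
  z, y, x order); canonicalization is idempotent. Exact eigenvalue ties get
  coherence 0 and the conventional axis $e_z$, never an exception.

## Cube-level ODFs, GFA and peaks

The volume is partitioned into non-overlapping analysis cubes (default
$100^3$ voxels, anchored at the origin, partial edge cubes dropped). Every
valid voxel projects its axis onto a fixed sampling of 6,500 unit
directions; half a voxel's weight goes to the bin nearest $+v$ and half to
the bin nearest $-v$. The sampling places 3,250 points on a hemisphere by a
golden-angle equal-area spiral and mirrors them, so antipodes are exact and
every ODF is antipodally symmetric by construction. Voxels are weighted by
count (default) or by coherence.

The dispersion of a discrete ODF $\psi$ over $n$ directions is summarized
by the standard generalized fractional anisotropy,

$$ \mathrm{GFA} \;=\;
   \sqrt{\frac{n \sum_i (\psi_i - \bar\psi)^2}{(n-1)\sum_i \psi_i^2}}, $$

which is exactly 0 when all orientations are equally represented and
exactly 1 when a single direction carries all weight.

Peaks are detected on a lightly smoothed ODF (one step of neighbor-graph
averaging, about the 2.5-degree bin spacing, to suppress bin noise): local
maxima on the k-nearest-neighbor graph with amplitude at least 0.3 of the
smoothed maximum become candidates, antipodal duplicates merge into a
single axis, and peaks are accepted greedily by amplitude subject to a
pairwise separation of at least 45 degrees. Two equal axes 90 degrees apart
therefore give two peaks; 30 degrees apart, one.

## Spatial organization: tensor-field autocorrelation

Orientation is axial, so correlation analysis uses the traceless dyadic
tensor $T(x) = v v^{\mathsf T} - I/3$ (identical for $v$ and $-v$; zero at
invalid voxels). Per cube, the masked mean tensor is subtracted and the 3D
autocorrelation is computed by the zero-padded FFT method per tensor
component, combined with the Frobenius inner product, and normalized by the
valid-pair count per lag and the zero-lag variance, so $C(0)=1$ and
$C(\Delta)=C(-\Delta)$. Pair-count normalization (rather than zero-filling)
keeps masked voxels from biasing the estimate toward zero. The spectral
path is verified against a direct-summation oracle to $10^{-10}$ in the
test suite. Cubes whose masked variance is below $10^{-8}$ (constant
orientation) are flagged homogeneous; their correlation length is reported
as the capped value.

The ACF is resampled into the cube's **fiber frame**: $e_1$ is the dominant
ODF peak, $e_2$ the second peak orthogonalized against $e_1$ (or a
deterministic perpendicular for single-peak cubes), $e_3 = e_1 \times e_2$.
Axial profiles follow the three frame axes; radially averaged profiles
cover the fiber plane $\mathrm{span}(e_1,e_2)$ and the transverse plane
$\mathrm{span}(e_2,e_3)$; a 2D transverse slice is kept for the laminar
screen. Profiles extend from 0 to half the cube extent ($50\,\mu m$ at
defaults), the reliable lag range.

Correlation lengths come from a least-squares fit of
$C(r) = e^{-r/\xi}$ on the log scale (slope through the origin, since
$C(0)=1$), over lags from one spacing up to the first lag where the profile
drops below 0.05. Profiles that never fall below $1/e$ are capped at the
window half-length and flagged; fewer than 5 usable points is a fit
failure. The **maximum autocorrelation length** of a cube is the maximum of
$\xi$ over the three frame axes — the spatial scale of organization mapped
across the tissue.

## The laminar periodicity screen

Laminar/orthogonal tissue leaves a specific signature: the transverse ACF
oscillates with the laminar period $\lambda$ while the along-fiber profile
decays smoothly. The screen works on the transverse radial profile:

1. The fitted exponential envelope is **subtracted** (not divided out),
   keeping the residual in correlation units. Division has to be clamped
   near zero and then amplifies the tail of decay-only profiles twenty-fold,
   destroying the amplitude scale the next criterion needs.
2. The residual is mean-subtracted, Hann-tapered, extended symmetrically to
   the full lag window $W$ (the ACF is even), and Fourier transformed.
3. The candidate is the strongest nonzero-frequency bin whose period lies
   in the searched band (default $10\,\mu m$ to $W/1.5$, the largest period
   the cycle rule allows). Four criteria must all pass:
   * **snr_1d**: candidate power at least 3 times the median power of the
     other nonzero bins;
   * **modulation**: oscillation amplitude at the peak at least 0.1 of the
     zero-lag correlation. ACF profiles have no white-noise floor —
     neighboring lags share most voxel pairs, so even decay-only profiles
     are smooth and their spectra are red; a pure power ratio passes on
     every cube, and an absolute depth in correlation units is what
     actually separates a real oscillation (depth ~0.3 on laminar cubes)
     from tail wiggle (~0.01–0.03 on bundles and meshwork);
   * **cycles**: $W \cdot f \ge 1.5$ full periods inside the window;
   * **snr_2d**: the 2D transverse power spectrum must show a peak at the
     matching radial frequency — the ring maximum at the candidate radius
     at least 3 times the median ring maximum at other radii.
4. The reported period is refined by parabolic interpolation across the 2D
   spectral rings when they match the 1D candidate. The azimuthal average
   disperses the oscillation (a $J_0$-like profile whose spectrum is skewed
   toward low frequencies), while the 2D slice holds a point peak at the
   true frequency; on default phantoms the 2D-refined estimate is accurate
   to a few percent where the 1D-only estimate errs by tens of percent.

A cube is labeled **laminar** exactly when the screen passes *and* its ODF
has at least two peaks; otherwise **bundled** when it has a single peak and
GFA at or above 0.4; otherwise **multi-orientation**. Removing the two-peak
requirement can only enlarge the laminar set (the classifier exposes the
switch so this is testable).

## Masking and maps

Cubes are masked from all spatial maps when their GFA falls below 0.4 (the
lower end of the displayed GFA range), when they touch the volume border
within a configurable margin, or when their valid-voxel fraction is too low
(tissue border). Masking is monotone in the GFA floor. Maps (GFA, maximum
correlation length, binary laminar, motif) are assembled on the block
lattice in deterministic z-major order, masked cells `NA`, and written as
CSV grids plus a PNG render with the fixed 0.4–1.0 GFA color scale.

Multiresolution inputs follow the factor-2 pyramid convention with
tissue-scale voxel sizes: a physical voxel of $0.75\,\mu m$ in a 3x-expanded
gel is $0.25\,\mu m$ of tissue at level 0, $0.5\,\mu m$ at level 1, and a
100-voxel cube at level 4 spans $0.4\,mm$ — the analysis-region scale.

## The phantom generator

`generatePhantom()` renders fibers as tubes with a radial Gaussian profile
(peak 1, scale = radius), combined across fibers by maximum — label
intensity saturates; staining is not additive. The geometry is then blurred
with a per-axis Gaussian PSF, a constant background is added, then Gaussian
noise, clipped at zero. Ground truth records, per voxel, the axial
direction of the nearest fiber wherever a tube interior covers the voxel
(`NA` elsewhere — never a zero-vector sentinel) plus a motif label.
Identical specifications are bit-identical.

Defaults, chosen once as a plausible desk-scale stand-in for labeled
white matter at micrometer resolution:

| parameter | default | rationale |
|---|---|---|
| voxel size | 1 um | tissue-scale resolution at which ~2 um axons are resolved |
| shape | 192^3 (tests use 120^3) | one-plus analysis cubes per volume |
| fiber radius | 1 um | large-caliber traceable axons |
| fill target | meshwork 0.05, laminar 0.10, bundled 0.20 | the observed progressive density increase across motifs |
| meshwork segment length | 30 um | ~1000 independent fiber directions per cube, giving the flat, multi-peak meshwork ODF |
| laminar period | 40 um (20–40 studied) | the organizational scale range |
| angular jitter | 3 deg half-normal | "nearly parallel" fibers |
| psf sigma | 1 um | lightsheet-class blur |
| noise sd / background | 0.05 / 0.02 of tube peak | visible but benign degradation |

Motif construction: meshwork fibers are finite segments at uniformly random
directions and positions; laminar space is sliced into slabs of thickness
$\lambda/2$ along the layer normal, fibers in slab $i$ parallel to layer
axis $i \bmod 2$ with *in-plane* jitter (rotation about the normal, so
fibers stay inside their slab — tilt jitter at $\lambda = 20\,\mu m$ would
let a single fiber cross slabs and blur the lamination); bundles are full
chords parallel to the bundle axis with 3D jitter. An optional
`curvatureAmp` bows each fiber smoothly (sampled into straight segments
whose local tangents become the ground truth); fibers are straight by
default.

What the phantoms do **not** emulate: axon caliber distributions, myelin or
label biophysics, expansion artifacts, tissue boundaries, curvature beyond
a single smooth bow, multi-channel stains, or the empirical density of real
white matter — the fill targets are free parameters, not tissue
calibration. Passing tests therefore demonstrate that the estimators
recover *known* geometry under *modeled* degradation; they do not certify
accuracy on real tissue.

Two consequences of the defaults are worth knowing. First, flat meshwork
ODFs imply meshwork GFA around 0.27, below the 0.4 map floor — meshwork
cubes are therefore masked as low-FA in spatial maps, exactly as low-FA
cubes are masked in tissue maps; their motif label is still computed and
tested before masking. Second, laminar detection at these settings is
robust far beyond the default noise: the suite asserts detection at the
default level and a non-increasing detection rate over a noise grid
reaching 1.5 times the tube peak amplitude (24 um period, 96 um window),
and detection at a 30 um period persists with noise at the full tube
amplitude.

## Problem sizes and numerics

The validation suite runs phantoms of $120^3$ voxels (one $100^3$ analysis
cube after border handling) for period recovery (periods 20/30/40 um) and
specificity (five seeds each of bundled and meshwork), a three-region
composite of $120 \times 120 \times 600$ voxels for motif classification,
and $100^3$ patchwork orientation fields (patch sizes 10/20/40 um) for
correlation-length recovery — sizes at which every stage's behavior is
measurable in minutes on a single core. Oracle comparisons (spectral vs
direct-summation ACF, windowed gradient sums) run on $8^3$–$10^3$ regions
at tolerances of $10^{-8}$ or tighter.

Numerical conventions collected in one place: arrays are `(z, y, x)`,
vectors `(x, y, z)`, 0-based voxel indices and half-open cubes in all
outputs; mirror boundary for all separable filtering; derivative kernels
normalized to unit response on a unit ramp; eigenvalues ascending;
zero-padding to side + max-lag so circular wraparound cannot contaminate
any reported lag; pair counts below one pair give `NA` correlation;
tie-breaks and degenerate cases (constant cubes, empty cubes, all-failed
fits) are explicit flagged states, never exceptions mid-pipeline.

## Known limitations

* One fiber population per voxel: crossing fibers inside a single voxel
  average into the tensor rather than splitting (the ODF handles crossings
  at the cube scale instead).
* The exponential ACF model is a summary, not a fit to truth: patchy or
  oscillating profiles yield low $R^2$, which is reported, and capped
  values flag profiles that do not decay inside the window.
* The laminar screen assumes one dominant period; multi-period laminae and
  wavelet-style analyses are out of scope.
* Correlation lengths saturate at the window half-length; structures
  organized beyond that scale need the super-cube window or larger cubes.
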