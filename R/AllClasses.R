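#' @include fiberarch-package.R
NULL

.isUnit <- function(v, tol = 1e-9) abs(sqrt(sum(v^2)) - 1) <= tol

# ---------------------------------------------------------------- phantom ---

#' Specification of a synthetic axon phantom
#'
#' Describes one of three organizational motifs of white-matter axons —
#' `"meshwork"` (low-density fibers with uniformly random directions),
#' `"laminar"` (alternating slabs of near-orthogonal parallel fibers with
#' spatial period `laminarPeriod`), or `"bundled"` (high-density
#' near-parallel fibers) — rendered as bright Gaussian-profile tubes on a
#' dark background with optical blur and noise. Create with [phantomSpec()].
#'
#' @slot motif character, one of `"meshwork"`, `"laminar"`, `"bundled"`.
#' @slot shape integer vector, voxels per axis in `(z, y, x)` order.
#' @slot voxelSize numeric, isotropic voxel size in um.
#' @slot fiberRadius numeric, tube radius in um (Gaussian radial scale).
#' @slot fiberLength numeric, fiber segment length in um (`Inf` = full
#'   chord through the volume).
#' @slot fillTarget numeric, target foreground voxel fraction; `NA` when
#'   `fiberCount` is given instead.
#' @slot fiberCount integer, explicit number of fibers (`NA` to use
#'   `fillTarget`).
#' @slot laminarPeriod numeric, laminar spatial period lambda in um (one
#'   full cycle = two slabs).
#' @slot layerNormal unit vector `(x,y,z)`, normal of the laminar slabs.
#' @slot layerAxes 2 x 3 matrix of unit vectors, fiber directions of
#'   alternating slabs; near-orthogonal, both near-perpendicular to
#'   `layerNormal`.
#' @slot bundleAxis unit vector `(x,y,z)`, common fiber axis of the bundled
#'   motif.
#' @slot angularJitterDeg numeric, half-normal sd of per-fiber angular
#'   jitter in degrees.
#' @slot curvatureAmp numeric, lateral bow amplitude in um of a smooth
#'   low-order curvature perturbation (0 = straight fibers, the default).
#' @slot psfSigma numeric length 3, Gaussian blur sigma in um per `(z,y,x)`
#'   axis.
#' @slot noiseSd numeric, additive Gaussian noise sd (intensity units).
#' @slot backgroundLevel numeric, additive background level.
#' @slot seed integer RNG seed; identical specs give bit-identical phantoms.
#' @seealso [generatePhantom()]
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  motif = "character", shape = "integer", voxelSize = "numeric",
  fiberRadius = "numeric", fiberLength = "numeric", fillTarget = "numeric",
  fiberCount = "integer", laminarPeriod = "numeric", layerNormal = "numeric",
  layerAxes = "matrix", bundleAxis = "numeric", angularJitterDeg = "numeric",
  curvatureAmp = "numeric", psfSigma = "numeric", noiseSd = "numeric",
  backgroundLevel = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!object@motif %in% c("meshwork", "laminar", "bundled"))
    msg <- c(msg, "motif must be meshwork, laminar or bundled")
  if (length(object@shape) != 3 || any(object@shape < 8))
    msg <- c(msg, "shape must be three axis lengths >= 8")
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be positive")
  if (object@fiberRadius < object@voxelSize / 2)
    msg <- c(msg, "fiberRadius must be >= voxelSize/2 (unresolvable tube)")
  if (object@angularJitterDeg < 0)
    msg <- c(msg, "angularJitterDeg must be >= 0")
  if (object@curvatureAmp < 0)
    msg <- c(msg, "curvatureAmp must be >= 0")
  if (object@motif == "laminar") {
    if (!is.finite(object@laminarPeriod) || object@laminarPeriod <= 0)
      msg <- c(msg, "laminarPeriod must be > 0 for the laminar motif")
    if (!.isUnit(object@layerNormal))
      msg <- c(msg, "layerNormal must be unit norm (within 1e-9)")
    if (nrow(object@layerAxes) != 2 ||
        !all(apply(object@layerAxes, 1, .isUnit)))
      msg <- c(msg, "layerAxes must be two unit vectors")
    else {
      sep <- acos(min(1, abs(sum(object@layerAxes[1, ] * object@layerAxes[2, ])))) * 180 / pi
      if (sep < 60 - 1e-9)
        msg <- c(msg, "layerAxes must be separated by >= 60 degrees")
    }
  }
  if (object@motif == "bundled" && !.isUnit(object@bundleAxis))
    msg <- c(msg, "bundleAxis must be unit norm (within 1e-9)")
  if (is.na(object@fiberCount) && !is.finite(object@fillTarget))
    msg <- c(msg, "one of fillTarget or fiberCount is required")
  if (length(object@psfSigma) != 3 || any(object@psfSigma < 0))
    msg <- c(msg, "psfSigma must be three nonnegative sigmas (z,y,x)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic axon phantom with voxel-level ground truth
#'
#' @slot volume 3D `(z,y,x)` intensity array, finite and nonnegative.
#' @slot truthAxis array `c(dim(volume), 3)`, per-voxel unit axial fiber
#'   direction in `(x,y,z)` component order; `NA` on background (no zero
#'   vector sentinel is ever used).
#' @slot truthMask logical array, `TRUE` exactly where a fiber tube interior
#'   (distance to axis <= radius) covers the voxel.
#' @slot truthMotif integer array, per-voxel motif code (1 = meshwork,
#'   2 = laminar, 3 = bundled) of the region the voxel belongs to.
#' @slot spec the generating [PhantomSpec-class] (first region spec for
#'   composites).
#' @exportClass Phantom
setClass("Phantom", representation(
  volume = "array", truthAxis = "array", truthMask = "array",
  truthMotif = "array", spec = "PhantomSpec"))

setValidity("Phantom", function(object) {
  d <- dim(object@volume)
  msg <- character()
  if (any(!is.finite(object@volume)) || any(object@volume < 0))
    msg <- c(msg, "volume must be finite and nonnegative")
  if (!identical(dim(object@truthMask), d) ||
      !identical(dim(object@truthMotif), d) ||
      !identical(dim(object@truthAxis), c(d, 3L)))
    msg <- c(msg, "ground-truth grids must match the volume shape")
  if (length(msg)) msg else TRUE
})

# ------------------------------------------------------------ orientation ---

#' Structure tensor scales
#'
#' @slot sigmaGradient derivative-of-Gaussian scale in um.
#' @slot sigmaWindow tensor window (smoothing) scale in um; must be >=
#'   `sigmaGradient`.
#' @exportClass StructureTensorParams
setClass("StructureTensorParams", representation(
  sigmaGradient = "numeric", sigmaWindow = "numeric"))

setValidity("StructureTensorParams", function(object) {
  if (object@sigmaGradient <= 0 || object@sigmaGradient > object@sigmaWindow)
    "requires 0 < sigmaGradient <= sigmaWindow" else TRUE
})

#' Per-voxel structure tensor field
#'
#' Symmetric 3x3 tensors stored as an array `c(dim, 6)` with component
#' order `(xx, yy, zz, xy, xz, yz)` in the `(x,y,z)` basis.
#'
#' @slot tensors array `c(dim, 6)`.
#' @slot voxelSize numeric length 3, `(z,y,x)` voxel size in um.
#' @slot params the [StructureTensorParams-class] used.
#' @exportClass TensorField
setClass("TensorField", representation(
  tensors = "array", voxelSize = "numeric", params = "StructureTensorParams"))

#' Per-voxel fiber orientation field
#'
#' @slot axis array `c(dim, 3)`, sign-canonicalized unit axial vectors in
#'   `(x,y,z)` component order (axial: `v` and `-v` are the same fiber
#'   orientation).
#' @slot coherence array, `(lambda2 - lambda1) / (lambda1+lambda2+lambda3)`
#'   clipped to `[0, 1]` (eigenvalues ascending).
#' @slot energy array, tensor trace (>= 0).
#' @slot valid logical array; `FALSE` at low-energy voxels and within the
#'   filter-support border margin.
#' @slot voxelSize numeric length 3, `(z,y,x)` voxel size in um.
#' @exportClass OrientationField
setClass("OrientationField", representation(
  axis = "array", coherence = "array", energy = "array", valid = "array",
  voxelSize = "numeric"))

setValidity("OrientationField", function(object) {
  d <- dim(object@coherence)
  msg <- character()
  if (!identical(dim(object@axis), c(d, 3L)))
    msg <- c(msg, "axis must have shape c(dim, 3)")
  if (!identical(dim(object@valid), d) || !identical(dim(object@energy), d))
    msg <- c(msg, "coherence/energy/valid shapes must agree")
  ch <- object@coherence[object@valid]
  if (length(ch) && (min(ch) < -1e-9 || max(ch) > 1 + 1e-9))
    msg <- c(msg, "coherence must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

# ------------------------------------------------------------- odf_blocks ---

#' Dense spherical sampling for discrete ODFs
#'
#' Antipodally symmetric equal-area (spiral) layout: the first `n/2`
#' directions cover the upper hemisphere, followed by their exact antipodes,
#' so the antipode map is an exact involution.
#'
#' @slot directions n x 3 matrix of unit vectors (`(x,y,z)` order).
#' @slot neighbors list of integer vectors, symmetric k-nearest-neighbor
#'   adjacency over directions.
#' @slot antipodeIndex integer vector, index of each direction's antipode.
#' @exportClass SphereSampling
setClass("SphereSampling", representation(
  directions = "matrix", neighbors = "list", antipodeIndex = "integer"))

setValidity("SphereSampling", function(object) {
  n <- nrow(object@directions)
  msg <- character()
  if (max(abs(sqrt(rowSums(object@directions^2)) - 1)) > 1e-9)
    msg <- c(msg, "directions must be unit vectors")
  a <- object@antipodeIndex
  if (length(a) != n || any(a[a] != seq_len(n)))
    msg <- c(msg, "antipodeIndex must be an involution")
  if (length(msg)) msg else TRUE
})

#' Analysis-cube partition of a voxel grid
#'
#' Non-overlapping by default (stride = block size), anchored at the volume
#' origin; partial edge blocks are dropped. Block indices are 0-based,
#' blocks are half-open voxel intervals.
#'
#' @slot blockSize integer, voxels per side (>= 16).
#' @slot offset integer length 3, origin offset in voxels `(z,y,x)`.
#' @slot stride integer, voxels between block origins.
#' @exportClass BlockGrid
setClass("BlockGrid", representation(
  blockSize = "integer", offset = "integer", stride = "integer"))

setValidity("BlockGrid", function(object) {
  msg <- character()
  if (object@blockSize < 16) msg <- c(msg, "blockSize must be >= 16")
  if (object@stride < 1) msg <- c(msg, "stride must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Discrete ODF of one analysis cube
#'
#' @slot psi numeric, nonnegative weights over the sphere directions,
#'   summing to 1 when the block is non-empty; antipodally symmetric.
#' @slot gfa generalized fractional anisotropy of `psi`, in `[0, 1]`.
#' @slot peaks p x 3 matrix of peak axes (sign-canonical representative of
#'   each antipodal pair), sorted by amplitude descending, pairwise
#'   separated by >= the peak-separation rule.
#' @slot peakAmplitudes numeric, smoothed ODF amplitude at each peak.
#' @slot nValid integer, contributing voxel count.
#' @slot blockIndex integer length 3, 0-based `(i,j,k)` block index along
#'   `(z,y,x)`.
#' @slot centerUm numeric length 3, physical block center in um `(z,y,x)`.
#' @slot empty logical, `TRUE` when no valid voxel contributed.
#' @exportClass BlockODF
setClass("BlockODF", representation(
  psi = "numeric", gfa = "numeric", peaks = "matrix",
  peakAmplitudes = "numeric", nValid = "integer", blockIndex = "integer",
  centerUm = "numeric", empty = "logical"))

setValidity("BlockODF", function(object) {
  msg <- character()
  if (!object@empty) {
    if (any(object@psi < 0)) msg <- c(msg, "psi must be nonnegative")
    if (abs(sum(object@psi) - 1) > 1e-9) msg <- c(msg, "psi must sum to 1")
    if (object@gfa < -1e-12 || object@gfa > 1 + 1e-12)
      msg <- c(msg, "gfa must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

# -------------------------------------------------------------------- acf ---

#' Orientation dyadic tensor field
#'
#' Per-voxel traceless tensor `T = v v' - I/3` (invariant under the axial
#' sign flip `v -> -v`), zero where invalid, stored as `c(dim, 6)` with
#' component order `(xx, yy, zz, xy, xz, yz)`.
#'
#' @slot comps array `c(dim, 6)`.
#' @slot valid logical array.
#' @slot voxelSize numeric length 3 `(z,y,x)` um.
#' @exportClass DyadicField
setClass("DyadicField", representation(
  comps = "array", valid = "array", voxelSize = "numeric"))

#' Normalized 3D autocorrelation of a tensor field
#'
#' @slot acf centered autocorrelation array over lags `-L..L` per axis;
#'   `acf[L+1, L+1, L+1]` is the zero lag (= 1 unless degenerate).
#' @slot lagSpacing numeric length 3, lag spacing in um per `(z,y,x)` axis.
#' @slot nPairs array, valid voxel-pair count per lag.
#' @slot variance0 numeric, zero-lag (masked) variance of the mean-subtracted
#'   tensor field.
#' @slot homogeneous logical, `TRUE` when `variance0` is below the
#'   degeneracy floor (constant field), in which case `C` is undefined.
#' @exportClass ACFVolume
setClass("ACFVolume", representation(
  acf = "array", lagSpacing = "numeric", nPairs = "array",
  variance0 = "numeric", homogeneous = "logical"))

#' Fiber-frame autocorrelation profiles
#'
#' @slot frame 3 x 3 matrix, rows `e1` (fiber axis), `e2`, `e3` in `(x,y,z)`
#'   component order; orthonormal.
#' @slot r numeric, strictly increasing lag grid in um starting at 0.
#' @slot axial 3 x length(r) matrix, profiles along `e1`, `e2`, `e3`.
#' @slot fiberPlaneRadial numeric, azimuthal average in `span(e1, e2)`.
#' @slot transverseRadial numeric, azimuthal average in `span(e2, e3)`.
#' @slot transverse2d square matrix, 2D slice of the ACF over
#'   `span(e2, e3)` on the `(-max(r)..max(r))` grid.
#' @exportClass ACFProfiles
setClass("ACFProfiles", representation(
  frame = "matrix", r = "numeric", axial = "matrix",
  fiberPlaneRadial = "numeric", transverseRadial = "numeric",
  transverse2d = "matrix"))

#' Exponential-decay correlation lengths of one analysis cube
#'
#' @slot xi numeric length 3, correlation length per frame axis in um
#'   (capped at the window half-length when the profile never decays).
#' @slot r2 numeric length 3, goodness of the log-linear fit per axis.
#' @slot capped logical length 3, cap flag per axis.
#' @slot fitRange 3 x 2 matrix, `[r_min, r_max]` um used per axis.
#' @slot xiMax numeric, `max(xi)` (the maximum autocorrelation length).
#' @exportClass CorrelationFit
setClass("CorrelationFit", representation(
  xi = "numeric", r2 = "numeric", capped = "logical", fitRange = "matrix",
  xiMax = "numeric"))

# ---------------------------------------------------------------- laminar ---

#' Thresholds of the laminar-periodicity screen
#'
#' @slot minCycles minimum number of full spatial cycles inside the profile
#'   window (dimensionless, >= 1; default 1.5).
#' @slot snr1d threshold on the 1D spectral peak signal-to-noise ratio.
#' @slot snr2d threshold on the 2D spectral ring signal-to-noise ratio.
#' @slot minModulation minimum oscillation amplitude of the detrended
#'   transverse profile at the spectral peak, as a fraction of the
#'   zero-lag correlation (dimensionless, in (0, 1)).
#' @slot periodBand numeric length 2, `[lambda_min, lambda_max]` um searched;
#'   `NA` upper bound means `window / minCycles` (forced by the cycle rule).
#' @exportClass PeriodicityCriteria
setClass("PeriodicityCriteria", representation(
  minCycles = "numeric", snr1d = "numeric", snr2d = "numeric",
  minModulation = "numeric", periodBand = "numeric"))

setValidity("PeriodicityCriteria", function(object) {
  msg <- character()
  if (object@minCycles < 1) msg <- c(msg, "minCycles must be >= 1")
  if (object@snr1d <= 1 || object@snr2d <= 1)
    msg <- c(msg, "SNR thresholds must be > 1")
  if (object@minModulation <= 0 || object@minModulation >= 1)
    msg <- c(msg, "minModulation must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Laminar periodicity decision for one analysis cube
#'
#' `isLaminar` is `TRUE` only when the profile window holds at least
#' `minCycles` full periods, both spectral SNRs pass, and (after
#' [classifyBlock()]) the ODF has at least two orientation peaks.
#'
#' @slot isLaminar logical.
#' @slot periodUm estimated spatial period lambda in um (`NA` if not
#'   periodic).
#' @slot snr1 1D spectral peak SNR.
#' @slot snr2 2D spectral ring SNR.
#' @slot nPeaks integer, ODF peak count (`NA` before classification).
#' @slot reasons character, names of failed criteria (empty when laminar).
#' @exportClass LaminarCall
setClass("LaminarCall", representation(
  isLaminar = "logical", periodUm = "numeric", snr1 = "numeric",
  snr2 = "numeric", nPeaks = "integer", reasons = "character"))

# ---------------------------------------------------------------- maps_io ---

#' Multiresolution pyramid metadata
#'
#' Voxel sizes refer to the unexpanded tissue: `baseVoxelUm =
#' physicalVoxelUm / expansionFactor`, and level-`L` voxels measure
#' `baseVoxelUm * 2^L`.
#'
#' @slot baseVoxelUm voxel size at level 0, um (tissue scale).
#' @slot level integer >= 0, pyramid level of the stored data.
#' @slot expansionFactor dimensionless gel expansion factor.
#' @slot physicalVoxelUm voxel size in the expanded gel, um.
#' @exportClass PyramidMeta
setClass("PyramidMeta", representation(
  baseVoxelUm = "numeric", level = "integer", expansionFactor = "numeric",
  physicalVoxelUm = "numeric"))

setValidity("PyramidMeta", function(object) {
  msg <- character()
  if (object@level < 0) msg <- c(msg, "level must be >= 0")
  if (abs(object@baseVoxelUm - object@physicalVoxelUm / object@expansionFactor) >
      1e-9 * object@baseVoxelUm)
    msg <- c(msg, "baseVoxelUm must equal physicalVoxelUm / expansionFactor")
  if (length(msg)) msg else TRUE
})
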