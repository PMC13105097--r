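#' @include AllClasses.R utils.R
NULL

.motifCode <- c(meshwork = 1L, laminar = 2L, bundled = 3L)

#' Create a synthetic axon phantom specification
#'
#' Builds a validated [PhantomSpec-class] with motif-appropriate defaults.
#' The three motifs emulate the organizational regimes observed in labeled
#' white matter: a low-density meshwork of uniformly random fiber segments,
#' alternating laminar slabs of near-orthogonal parallel fibers with spatial
#' period `laminarPeriod`, and a high-density bundle of near-parallel
#' fibers. Default fill targets (meshwork 0.05, laminar 0.10, bundled 0.20)
#' reproduce the progressive density increase from meshwork through laminar
#' to bundled tissue; meshwork fibers are short segments (30 um) so that a
#' single analysis cube holds enough independent fiber directions to show
#' the flat, multi-peak ODF of a true multi-orientation meshwork.
#'
#' @param motif `"meshwork"`, `"laminar"` or `"bundled"`.
#' @param shape voxels per axis, `(z, y, x)`; default `c(192, 192, 192)`.
#' @param voxelSize isotropic voxel size in um (default 1).
#' @param fiberRadius tube radius in um (default 1; Gaussian radial scale).
#' @param fiberLength fiber segment length in um; default 30 for meshwork,
#'   `Inf` (full chord) otherwise.
#' @param fillTarget target foreground voxel fraction; motif default used
#'   when `NULL` and `fiberCount` is absent.
#' @param fiberCount explicit fiber count overriding `fillTarget`.
#' @param laminarPeriod laminar spatial period lambda in um (default 40).
#' @param layerNormal,layerAxes,bundleAxis motif geometry; see
#'   [PhantomSpec-class].
#' @param angularJitterDeg half-normal sd of per-fiber angular jitter in
#'   degrees (default 3).
#' @param curvatureAmp lateral bow amplitude in um of a smooth low-order
#'   curvature perturbation per fiber; 0 (default) keeps fibers straight.
#' @param psfSigma Gaussian blur sigma in um, scalar or per `(z,y,x)` axis
#'   (default 1).
#' @param noiseSd additive Gaussian noise sd (default 0.05; tube peak
#'   amplitude is 1).
#' @param backgroundLevel additive background (default 0.02).
#' @param seed integer RNG seed (default 1).
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec("laminar", shape = c(64, 64, 64), laminarPeriod = 20)
#' spec
#' @export
phantomSpec <- function(motif = c("meshwork", "laminar", "bundled"),
                        shape = c(192L, 192L, 192L), voxelSize = 1,
                        fiberRadius = 1, fiberLength = NULL,
                        fillTarget = NULL, fiberCount = NA_integer_,
                        laminarPeriod = 40,
                        layerNormal = c(0, 0, 1),
                        layerAxes = rbind(c(1, 0, 0), c(0, 1, 0)),
                        bundleAxis = c(1, 0, 0),
                        angularJitterDeg = 3, curvatureAmp = 0,
                        psfSigma = 1, noiseSd = 0.05,
                        backgroundLevel = 0.02, seed = 1L) {
  motif <- match.arg(motif)
  if (is.null(fillTarget))
    fillTarget <- c(meshwork = 0.05, laminar = 0.10, bundled = 0.20)[[motif]]
  if (is.null(fiberLength))
    fiberLength <- if (motif == "meshwork") 30 else Inf
  if (length(psfSigma) == 1) psfSigma <- rep(psfSigma, 3)
  new("PhantomSpec", motif = motif, shape = as.integer(shape),
      voxelSize = as.numeric(voxelSize), fiberRadius = as.numeric(fiberRadius),
      fiberLength = as.numeric(fiberLength),
      fillTarget = as.numeric(fillTarget), fiberCount = as.integer(fiberCount),
      laminarPeriod = as.numeric(laminarPeriod),
      layerNormal = as.numeric(layerNormal),
      layerAxes = matrix(as.numeric(layerAxes), nrow = 2),
      bundleAxis = as.numeric(bundleAxis),
      angularJitterDeg = as.numeric(angularJitterDeg),
      curvatureAmp = as.numeric(curvatureAmp),
      psfSigma = as.numeric(psfSigma), noiseSd = as.numeric(noiseSd),
      backgroundLevel = as.numeric(backgroundLevel), seed = as.integer(seed))
}

# Perpendicular orthonormal pair for a unit vector (deterministic).
.perpBasis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- ref - sum(ref * u) * u
  p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(u[2] * p1[3] - u[3] * p1[2],
          u[3] * p1[1] - u[1] * p1[3],
          u[1] * p1[2] - u[2] * p1[1])
  rbind(p1, p2)
}

# Tilt axis u by angle ~ half-normal(sigmaDeg), uniform azimuth.
.jitterAxis <- function(u, sigmaDeg) {
  if (sigmaDeg <= 0) return(u)
  ang <- abs(rnorm(1, 0, sigmaDeg)) * pi / 180
  phi <- runif(1, 0, 2 * pi)
  P <- .perpBasis(u)
  v <- cos(ang) * u + sin(ang) * (cos(phi) * P[1, ] + sin(phi) * P[2, ])
  v / sqrt(sum(v^2))
}

# In-plane jitter: rotate u about the layer normal n by a signed angle.
# Keeps laminar fibers inside their slab.
.jitterInPlane <- function(u, n, sigmaDeg) {
  if (sigmaDeg <= 0) return(u)
  ang <- rnorm(1, 0, sigmaDeg) * pi / 180
  # Rodrigues rotation about n
  cx <- c(n[2] * u[3] - n[3] * u[2],
          n[3] * u[1] - n[1] * u[3],
          n[1] * u[2] - n[2] * u[1])
  v <- u * cos(ang) + cx * sin(ang) + n * sum(n * u) * (1 - cos(ang))
  v / sqrt(sum(v^2))
}

# Draw one batch of fibers for a motif and decompose them into straight
# segments. Positions in um, (x,y,z). Returns list(p0, p1, axis), one row
# per SEGMENT (curved fibers contribute several; the per-segment axis is
# the local tangent, which becomes the voxel ground truth).
.drawFibers <- function(spec, n) {
  ext <- rev(spec@shape - 1L) * spec@voxelSize # (x,y,z) extent in um
  ctr <- cbind(runif(n, 0, ext[1]), runif(n, 0, ext[2]), runif(n, 0, ext[3]))
  # chord just beyond the volume diagonal: crosses the volume from any
  # center, and a curvature bow spans mostly visible length
  half <- min(spec@fiberLength, 1.2 * sqrt(sum(ext^2))) / 2
  axes <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    axes[i, ] <- switch(spec@motif,
      meshwork = {
        u <- rnorm(3)
        u / sqrt(sum(u^2))
      },
      laminar = {
        slab <- floor(sum(ctr[i, ] * spec@layerNormal) /
                        (spec@laminarPeriod / 2))
        base <- spec@layerAxes[(slab %% 2) + 1, ]
        .jitterInPlane(base, spec@layerNormal, spec@angularJitterDeg)
      },
      bundled = .jitterAxis(spec@bundleAxis, spec@angularJitterDeg))
  }
  if (spec@curvatureAmp <= 0)
    return(list(p0 = ctr - half * axes, p1 = ctr + half * axes, axis = axes))

  # smooth single-bow curvature: lateral sine offset in a random
  # perpendicular direction, sampled into straight segments
  nSeg <- 8L
  tt <- seq(0, 1, length.out = nSeg + 1L)
  P0 <- P1 <- AX <- vector("list", n)
  for (i in seq_len(n)) {
    P <- .perpBasis(axes[i, ])
    phi <- runif(1, 0, 2 * pi)
    lat <- cos(phi) * P[1, ] + sin(phi) * P[2, ]
    pts <- outer(rep(1, nSeg + 1L), ctr[i, ]) +
      outer((tt - 0.5) * 2 * half, axes[i, ]) +
      outer(spec@curvatureAmp * sin(pi * tt), lat)
    dif <- pts[-1, , drop = FALSE] - pts[-(nSeg + 1L), , drop = FALSE]
    P0[[i]] <- pts[-(nSeg + 1L), , drop = FALSE]
    P1[[i]] <- pts[-1, , drop = FALSE]
    AX[[i]] <- unitRows(dif)
  }
  list(p0 = do.call(rbind, P0), p1 = do.call(rbind, P1),
       axis = do.call(rbind, AX))
}

# Merge a freshly rendered batch into running render state.
.mergeRender <- function(state, batch, idOffset) {
  better <- batch$intensity > state$intensity
  state$intensity[better] <- batch$intensity[better]
  state$dist[better] <- batch$dist[better]
  state$fiberId[better] <- batch$fiberId[better] + idOffset
  state
}

#' Generate a synthetic axon phantom
#'
#' Renders fibers as tubes with a radial Gaussian intensity profile (peak
#' amplitude 1, scale = `fiberRadius`), combined across fibers by maximum
#' (labels saturate), then applies optical blur, background and noise via
#' [addImagingNoise()]. Ground truth is recorded per voxel: the axial
#' direction of the nearest fiber wherever a tube interior (distance <=
#' radius) covers the voxel, `NA` elsewhere. Fibers are added in batches
#' until the foreground voxel fraction reaches `fillTarget` (or exactly
#' `fiberCount` fibers are placed). Identical specs (including seed) give
#' bit-identical phantoms.
#'
#' @param spec a [PhantomSpec-class].
#' @param maxBatches iteration cap of the fill loop; if the target is not
#'   reached the call fails naming the achieved density.
#' @return A [Phantom-class].
#' @examples
#' ph <- generatePhantom(phantomSpec("bundled", shape = c(48, 48, 48),
#'                                   angularJitterDeg = 0, seed = 7))
#' ph
#' @export
generatePhantom <- function(spec, maxBatches = 60L) {
  validObject(spec)
  withSeed(spec@seed, {
    dimZyx <- spec@shape
    nvox <- prod(dimZyx)
    support <- 3 * spec@fiberRadius / spec@voxelSize # voxels
    rVox <- spec@fiberRadius / spec@voxelSize
    state <- list(intensity = array(0, dimZyx),
                  fiberId = array(0L, dimZyx),
                  dist = array(Inf, dimZyx))
    axes <- matrix(numeric(), 0, 3)

    ext <- rev(dimZyx - 1L) * spec@voxelSize
    meanLen <- min(spec@fiberLength, 0.7 * mean(ext))
    perFiber <- max(1, pi * rVox^2 * meanLen / spec@voxelSize)

    if (!is.na(spec@fiberCount)) {
      fib <- .drawFibers(spec, spec@fiberCount)
      batch <- .renderTubes(dimZyx, fib$p0 / spec@voxelSize,
                            fib$p1 / spec@voxelSize, rVox, support)
      state <- .mergeRender(state, batch, 0L)
      axes <- fib$axis
    } else {
      target <- spec@fillTarget
      for (it in seq_len(maxBatches)) {
        cur <- mean(state$dist <= rVox)
        if (cur >= target) break
        nAdd <- max(4L, as.integer(ceiling((target - cur) * nvox / perFiber)))
        fib <- .drawFibers(spec, nAdd)
        batch <- .renderTubes(dimZyx, fib$p0 / spec@voxelSize,
                              fib$p1 / spec@voxelSize, rVox, support)
        state <- .mergeRender(state, batch, nrow(axes))
        axes <- rbind(axes, fib$axis)
      }
      achieved <- mean(state$dist <= rVox)
      if (achieved < target)
        stop(sprintf(
          "fill target %.3g unreachable within %d batches (achieved density %.4g)",
          target, maxBatches, achieved))
    }

    mask <- state$dist <= rVox
    truthAxis <- array(NA_real_, c(dimZyx, 3L))
    if (any(mask)) {
      idx <- which(mask)
      fid <- state$fiberId[idx]
      ax <- canonicalizeAxes(axes[fid, , drop = FALSE])
      for (cmp in 1:3) {
        slice <- array(NA_real_, dimZyx)
        slice[idx] <- ax[, cmp]
        truthAxis[, , , cmp] <- slice
      }
    }
    vol <- addImagingNoise(state$intensity, psfSigma = spec@psfSigma,
                           noiseSd = spec@noiseSd,
                           backgroundLevel = spec@backgroundLevel,
                           voxelSize = spec@voxelSize, seed = NULL)
    new("Phantom", volume = vol, truthAxis = truthAxis, truthMask = mask,
        truthMotif = array(.motifCode[[spec@motif]], dimZyx), spec = spec)
  })
}

#' Render fiber polylines into a canvas volume
#'
#' Each fiber contributes a radially Gaussian-profiled tube (peak amplitude
#' 1, radial scale = `radius`); overlapping fibers and the existing canvas
#' combine by maximum. Paths extending beyond the canvas are clipped.
#'
#' @param paths list of polylines, each an n x 3 matrix of `(x, y, z)`
#'   points in um (n >= 2).
#' @param radius tube radius in um; must be >= `voxelSize / 2`, otherwise
#'   the tube is unresolvable and the call fails.
#' @param canvas 3D `(z,y,x)` array to draw onto.
#' @param voxelSize isotropic voxel size in um.
#' @return The canvas array with tubes max-combined in.
#' @export
renderFibers <- function(paths, radius, canvas, voxelSize = 1) {
  if (radius < voxelSize / 2)
    stop("radius must be >= voxelSize/2 (unresolvable tube)")
  if (length(paths) == 0) return(canvas)
  segs0 <- list(); segs1 <- list()
  for (p in paths) {
    p <- as.matrix(p)
    if (ncol(p) != 3 || nrow(p) < 2) stop("each path must be an n x 3 matrix, n >= 2")
    segs0[[length(segs0) + 1]] <- p[-nrow(p), , drop = FALSE]
    segs1[[length(segs1) + 1]] <- p[-1, , drop = FALSE]
  }
  p0 <- do.call(rbind, segs0) / voxelSize
  p1 <- do.call(rbind, segs1) / voxelSize
  out <- .renderTubes(dim(canvas), p0, p1, radius / voxelSize,
                      3 * radius / voxelSize)
  pmax(canvas, out$intensity)
}

#' Apply imaging blur and noise to a volume
#'
#' Gaussian blur with per-axis sigma (emulating the lightsheet PSF), then
#' additive background, then additive Gaussian noise, clipped at zero.
#'
#' @param volume 3D `(z,y,x)` array.
#' @param psfSigma blur sigma in um, scalar or per `(z,y,x)` axis; 0 skips
#'   the blur.
#' @param noiseSd additive Gaussian noise sd.
#' @param backgroundLevel additive background level.
#' @param voxelSize voxel size in um, scalar or `(z,y,x)`.
#' @param seed optional RNG seed; `NULL` uses the current RNG state.
#' @return The degraded volume (same shape, nonnegative).
#' @export
addImagingNoise <- function(volume, psfSigma = 1, noiseSd = 0.05,
                            backgroundLevel = 0.02, voxelSize = 1,
                            seed = NULL) {
  stopifnot(all(is.finite(volume)))
  vs <- voxelSize3(voxelSize)
  if (length(psfSigma) == 1) psfSigma <- rep(psfSigma, 3)
  if (any(psfSigma < 0) || noiseSd < 0)
    stop("psfSigma and noiseSd must be nonnegative")
  run <- function() {
    out <- volume
    if (any(psfSigma > 0)) out <- convSep3(out, psfSigma / vs)
    out <- out + backgroundLevel
    if (noiseSd > 0) out <- out + rnorm(length(out), 0, noiseSd)
    dim(out) <- dim(volume)
    pmax(out, 0)
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

#' Generate a composite phantom of several motif regions
#'
#' Concatenates independently generated phantoms along one axis, keeping
#' per-voxel ground truth (orientation, mask, motif label). All specs must
#' agree on voxel size and on the two non-concatenated axis lengths.
#'
#' @param specs list of [PhantomSpec-class] objects, one per region.
#' @param along array axis to concatenate on: 1 = z, 2 = y, 3 = x
#'   (default).
#' @return A [Phantom-class] whose `truthMotif` labels each region.
#' @export
compositePhantom <- function(specs, along = 3L) {
  stopifnot(length(specs) >= 2)
  parts <- lapply(specs, generatePhantom)
  other <- setdiff(1:3, along)
  d0 <- dim(parts[[1]]@volume)
  for (p in parts)
    if (!all(dim(p@volume)[other] == d0[other]))
      stop("region shapes must agree on the non-concatenated axes")
  dtot <- d0
  dtot[along] <- sum(vapply(parts, function(p) dim(p@volume)[along], 0L))
  bindA <- function(get, init, ncomp = NULL) {
    dd <- if (is.null(ncomp)) dtot else c(dtot, ncomp)
    out <- array(init, dd)
    at <- 0L
    for (p in parts) {
      block <- get(p)
      n <- dim(p@volume)[along]
      ix <- lapply(seq_along(dd), function(a) seq_len(dd[a]))
      ix[[along]] <- at + seq_len(n)
      out <- do.call(`[<-`, c(list(out), ix, list(value = block)))
      at <- at + n
    }
    out
  }
  new("Phantom",
      volume = bindA(function(p) p@volume, 0),
      truthAxis = bindA(function(p) p@truthAxis, NA_real_, 3L),
      truthMask = bindA(function(p) p@truthMask, FALSE),
      truthMotif = bindA(function(p) p@truthMotif, NA_integer_),
      spec = specs[[1]])
}

#' Orientation field with patchwise-constant random orientations
#'
#' Builds an [OrientationField-class] directly (no imaging step) whose
#' axial orientation is constant within cubic patches of side
#' `patchSizeUm` and drawn uniformly on the sphere per patch. Used to
#' validate correlation-length recovery: the recovered maximum
#' autocorrelation length should grow with the patch size.
#'
#' @param shape voxels per `(z,y,x)` axis.
#' @param patchSizeUm patch side in um.
#' @param voxelSize isotropic voxel size in um.
#' @param seed RNG seed.
#' @return An [OrientationField-class] with all voxels valid.
#' @export
patchworkOrientationField <- function(shape, patchSizeUm, voxelSize = 1,
                                      seed = 1L) {
  shape <- as.integer(shape)
  pvox <- max(1L, as.integer(round(patchSizeUm / voxelSize)))
  np <- ceiling(shape / pvox)
  withSeed(seed, {
    U <- matrix(rnorm(3 * prod(np)), ncol = 3)
    U <- canonicalizeAxes(unitRows(U))
    pid <- array(0L, shape)
    iz <- (seq_len(shape[1]) - 1L) %/% pvox
    iy <- (seq_len(shape[2]) - 1L) %/% pvox
    ix <- (seq_len(shape[3]) - 1L) %/% pvox
    pid <- outer(outer(iz, iy * np[1], `+`), ix * np[1] * np[2], `+`) + 1L
    dim(pid) <- shape
    ax <- array(0, c(shape, 3L))
    for (cmp in 1:3) ax[, , , cmp] <- array(U[pid, cmp], shape)
    new("OrientationField", axis = ax,
        coherence = array(1, shape), energy = array(1, shape),
        valid = array(TRUE, shape), voxelSize = rep(voxelSize, 3))
  })
}
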