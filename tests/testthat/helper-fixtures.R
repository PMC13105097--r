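# Shared fixtures, memoized across test files (testthat sources helpers
# into one session; heavy phantom pipelines are built once and reused).

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(builder())
  .fx[[name]]
}

fxSphere <- function() fx("sphere6500", function() fiberarch:::defaultSphere())

# Build the orientation field of a default phantom at study scale (120^3,
# one 100^3 analysis cube). NOT cached by default: a 120^3 phantom plus
# field holds ~170 MB, and the suite visits over a dozen conditions, so
# only the few conditions other test files re-visit are kept (see
# fxMeshworkField below).
buildField <- function(motif, seed = 1L, lam = 30, noiseSd = 0.05,
                       shape = c(120L, 120L, 120L)) {
  spec <- if (motif == "laminar")
    phantomSpec("laminar", shape = shape, laminarPeriod = lam,
                noiseSd = noiseSd, seed = seed)
  else phantomSpec(motif, shape = shape, noiseSd = noiseSd, seed = seed)
  ph <- generatePhantom(spec)
  fld <- principalOrientation(computeStructureTensor(ph@volume,
                                                     spec@voxelSize))
  list(phantom = ph, field = fld)
}

# The default meshwork field is reused across files; keep this one.
fxMeshworkField <- function() {
  fx("field_meshwork_1", function() buildField("meshwork", seed = 1L))
}

# Per-cube analysis of a phantom condition; only the (small) analysis
# result is cached, the phantom and field are discarded.
fxAnalysis <- function(motif, seed = 1L, lam = 30, noiseSd = 0.05,
                       shape = c(120L, 120L, 120L)) {
  key <- paste("an", motif, seed, lam, noiseSd,
               paste(shape, collapse = "x"), sep = "_")
  fx(key, function() {
    f <- if (motif == "meshwork" && seed == 1L && noiseSd == 0.05 &&
             identical(shape, c(120L, 120L, 120L)))
      fxMeshworkField() else buildField(motif, seed, lam, noiseSd, shape)
    an <- analyzeArchitecture(f$field, sphere = fxSphere(),
                              params = list(block_size = min(100L, min(shape))))
    rm(f)
    an
  })
}

# Composite three-region phantom (meshwork | laminar | bundled along x,
# two 100^3 cubes per region): cache the analysis and the per-voxel motif
# labels only; the volume and field are transient.
fxComposite <- function() {
  fx("composite", function() {
    specs <- list(
      phantomSpec("meshwork", shape = c(120L, 120L, 200L), seed = 11L),
      phantomSpec("laminar", shape = c(120L, 120L, 200L),
                  laminarPeriod = 30, seed = 12L),
      phantomSpec("bundled", shape = c(120L, 120L, 200L),
                  bundleAxis = c(0, 1, 0), seed = 13L))
    ph <- compositePhantom(specs, along = 3L)
    truthMotif <- ph@truthMotif
    fld <- principalOrientation(computeStructureTensor(ph@volume, 1))
    rm(ph)
    an <- analyzeArchitecture(fld, sphere = fxSphere())
    rm(fld)
    list(truthMotif = truthMotif, analysis = an)
  })
}

# Direct-summation masked tensor autocorrelation (independent oracle for
# the spectral path). Returns the centered, normalized lag array -L..L.
bruteForceACF <- function(dyadic, L) {
  d <- dim(dyadic@valid)
  w6 <- c(1, 1, 1, 2, 2, 2)
  mask <- dyadic@valid * 1
  nv <- sum(mask)
  mu <- vapply(1:6, function(c6) sum(dyadic@comps[, , , c6] * mask) / nv, 0)
  G <- array(0, c(d, 6))
  for (c6 in 1:6) G[, , , c6] <- (dyadic@comps[, , , c6] - mu[c6]) * mask
  C <- array(NA_real_, c(2 * L + 1, 2 * L + 1, 2 * L + 1))
  for (lz in -L:L) for (ly in -L:L) for (lx in -L:L) {
    z1 <- max(1, 1 - lz):min(d[1], d[1] - lz)
    y1 <- max(1, 1 - ly):min(d[2], d[2] - ly)
    x1 <- max(1, 1 - lx):min(d[3], d[3] - lx)
    np <- sum(mask[z1, y1, x1] * mask[z1 + lz, y1 + ly, x1 + lx])
    if (np == 0) next
    s <- 0
    for (c6 in 1:6)
      s <- s + w6[c6] * sum(G[z1, y1, x1, c6] * G[z1 + lz, y1 + ly, x1 + lx, c6])
    C[lz + L + 1, ly + L + 1, lx + L + 1] <- s / np
  }
  C / C[L + 1, L + 1, L + 1]
}

# Synthetic orientation field with a single constant axis.
constantField <- function(d, v, valid = NULL, voxelSize = 1) {
  if (is.null(valid)) valid <- array(TRUE, d)
  v <- v / sqrt(sum(v^2))
  ax <- array(0, c(d, 3L))
  for (cmp in 1:3) ax[, , , cmp] <- v[cmp]
  new("OrientationField", axis = ax, coherence = array(1, d),
      energy = array(1, d), valid = valid, voxelSize = rep(voxelSize, 3))
}

# Synthetic ACF profiles for the periodicity screen: transverse profile
# p(r) plus a separable 2D slice oscillating along e3 with the same period
# and envelope.
syntheticProfiles <- function(r, transverse, periodUm = NA, envelopeXi = Inf) {
  k <- length(r) - 1L
  spacing <- r[2] - r[1]
  g <- seq(-k, k) * spacing
  t2 <- outer(g, g, function(u, v) {
    rho <- sqrt(u^2 + v^2)
    base <- if (is.finite(envelopeXi)) exp(-rho / envelopeXi) else 1
    if (is.na(periodUm)) base else cos(2 * pi * v / periodUm) * base
  })
  new("ACFProfiles", frame = diag(3), r = r,
      axial = rbind(e1 = transverse, e2 = transverse, e3 = transverse),
      fiberPlaneRadial = transverse, transverseRadial = transverse,
      transverse2d = t2)
}

# Median angular error of an orientation field against a known axis over
# the phantom foreground.
medianAxisError <- function(field, truthMask, axis) {
  n <- prod(dim(field@coherence))
  vi <- which(validMask(field) & truthMask)
  V <- cbind(field@axis[vi], field@axis[vi + n], field@axis[vi + 2 * n])
  median(fiberarch:::axialAngleDeg(V, matrix(axis, length(vi), 3,
                                             byrow = TRUE)))
}

# Clean (noise-free) oblique bundle at 48^3 reused by orientation tests.
fxCleanBundle48 <- function() {
  fx("cleanBundle48", function() {
    u <- c(1, 2, 2) / 3
    ph <- generatePhantom(phantomSpec("bundled", shape = c(48, 48, 48),
                                      bundleAxis = u, angularJitterDeg = 0,
                                      noiseSd = 0, backgroundLevel = 0,
                                      seed = 5))
    list(phantom = ph,
         field = principalOrientation(computeStructureTensor(ph@volume, 1)))
  })
}
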