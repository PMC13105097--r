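# Internal numeric helpers shared across modules.

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Sampled Gaussian kernel, unit sum; sigma in voxels. sigma ~ 0 -> identity.
gaussKernel1d <- function(sigmaVox) {
  if (sigmaVox < 1e-8) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  u <- (-r):r
  k <- exp(-u^2 / (2 * sigmaVox^2))
  k / sum(k)
}

# Derivative-of-Gaussian kernel normalized so that correlating a unit ramp
# (in voxel index units) yields exactly 1.
dogKernel1d <- function(sigmaVox) {
  stopifnot(sigmaVox > 0)
  r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  u <- (-r):r
  raw <- u * exp(-u^2 / (2 * sigmaVox^2))
  raw <- raw - sum(raw) / length(raw) # exactly zero response on constants
  raw / sum(raw * u)
}

# Separable 3D Gaussian filtering; sigmaVox per axis in (z,y,x) order.
# deriv = 0 for plain smoothing, or the axis (1=z, 2=y, 3=x) that gets the
# derivative kernel instead of the smoothing kernel.
convSep3 <- function(arr, sigmaVox, deriv = 0L) {
  stopifnot(length(sigmaVox) == 3)
  out <- arr
  for (ax in 1:3) {
    k <- if (deriv == ax) dogKernel1d(sigmaVox[ax]) else gaussKernel1d(sigmaVox[ax])
    if (length(k) > 1L || deriv == ax) out <- .convAxis(out, as.numeric(k), ax)
  }
  out
}

# Sign-canonicalize axial vectors (rows of an n x 3 matrix, (x,y,z) order):
# flip so the largest-magnitude component is positive; ties broken by axis
# order z, y, x. Zero rows are left untouched.
canonicalizeAxes <- function(V) {
  if (is.null(dim(V))) V <- matrix(V, ncol = 3)
  a <- abs(V)
  m <- pmax(a[, 1], a[, 2], a[, 3])
  pick <- ifelse(a[, 3] == m, 3L, ifelse(a[, 2] == m, 2L, 1L))
  sgn <- sign(V[cbind(seq_len(nrow(V)), pick)])
  sgn[sgn == 0] <- 1
  V * sgn
}

unitRows <- function(V) {
  n <- sqrt(rowSums(V^2))
  n[n == 0] <- 1
  V / n
}

# Angle (degrees) between axes (orientation = sign-free), rowwise.
axialAngleDeg <- function(U, V) {
  if (is.null(dim(U))) U <- matrix(U, ncol = 3)
  if (is.null(dim(V))) V <- matrix(V, ncol = 3)
  d <- pmin(1, abs(rowSums(U * V)))
  acos(d) * 180 / pi
}

# Trilinear interpolation of a 3D array at fractional 1-based indices.
# pts: n x 3 matrix of (i1, i2, i3) array coordinates. NA outside.
trilinearSample <- function(arr, pts) {
  d <- dim(arr)
  i0 <- floor(pts)
  ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
    pts[, 2] >= 1 & pts[, 2] <= d[2] &
    pts[, 3] >= 1 & pts[, 3] <= d[3]
  # clamp the base corner so all eight samples stay in range
  i0[, 1] <- pmax(1, pmin(i0[, 1], d[1] - 1L))
  i0[, 2] <- pmax(1, pmin(i0[, 2], d[2] - 1L))
  i0[, 3] <- pmax(1, pmin(i0[, 3], d[3] - 1L))
  f <- pts - i0
  f[] <- pmax(0, pmin(1, f)) # keep the dim attribute
  val <- numeric(nrow(pts))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dx) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + dz, i0[, 2] + dy, i0[, 3] + dx)
    val <- val + w * arr[idx]
  }
  val[!ok] <- NA_real_
  val
}

# Normalize a voxel size argument to a length-3 (z,y,x) positive vector.
voxelSize3 <- function(voxelSize) {
  v <- as.numeric(voxelSize)
  if (length(v) == 1) v <- rep(v, 3)
  if (length(v) != 3 || any(!is.finite(v)) || any(v <= 0))
    stop("voxelSize must be a positive scalar or length-3 (z,y,x) vector in um")
  v
}

isIsotropic <- function(v3, tol = 1e-9) {
  diff(range(v3)) <= tol * mean(v3)
}
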