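#' @include AllClasses.R utils.R sphere.R
NULL

#' Define an analysis-cube partition
#'
#' @param blockSize voxels per cube side (default 100, >= 16).
#' @param offset origin offset in voxels, scalar or `(z,y,x)`.
#' @param stride voxels between block origins; defaults to `blockSize`
#'   (non-overlapping cubes).
#' @return A [BlockGrid-class].
#' @export
blockGrid <- function(blockSize = 100L, offset = 0L, stride = blockSize) {
  if (length(offset) == 1) offset <- rep(offset, 3)
  new("BlockGrid", blockSize = as.integer(blockSize),
      offset = as.integer(offset), stride = as.integer(stride))
}

# 0-based block origins fitting fully inside dims (partial blocks dropped).
blockOrigins <- function(dims, grid) {
  lapply(1:3, function(a) {
    if (dims[a] < grid@offset[a] + grid@blockSize) return(integer(0))
    o <- seq(grid@offset[a], dims[a] - grid@blockSize, by = grid@stride)
    as.integer(o[o >= 0])
  })
}

#' Accumulate discrete ODFs over analysis cubes
#'
#' Partitions the orientation field into cubes and projects every valid
#' voxel's axial orientation onto the sphere sampling: each axis `v` adds
#' half its weight to the direction bin nearest `+v` and half to the bin
#' nearest `-v` (exact antipodal bins by construction), so each cube's
#' discrete ODF `psi` is antipodally symmetric and normalized to sum 1.
#' Weights are 1 per voxel (`"count"`, default) or the voxel coherence
#' (`"coherence"`). Cubes without any valid voxel are flagged empty. GFA
#' and separation-constrained peaks are computed per cube.
#'
#' @param field an [OrientationField-class].
#' @param grid a [BlockGrid-class]; the field must contain at least one
#'   full block.
#' @param sphere a [SphereSampling-class]; default the cached 6500-point
#'   sampling.
#' @param weighting `"count"` or `"coherence"`.
#' @param minSeparationDeg,relAmplitude peak detection settings, see
#'   [findOdfPeaks()].
#' @return List of [BlockODF-class], one per full block, in z-fastest
#'   (z-major) block order.
#' @export
accumulateODF <- function(field, grid = blockGrid(), sphere = defaultSphere(),
                          weighting = c("count", "coherence"),
                          minSeparationDeg = 45, relAmplitude = 0.3) {
  weighting <- match.arg(weighting)
  stopifnot(is(field, "OrientationField"))
  d <- dim(field@coherence)
  org <- blockOrigins(d, grid)
  if (any(lengths(org) == 0))
    stop("field smaller than one analysis cube")
  B <- grid@blockSize
  nDir <- nrow(sphere@directions)
  m <- length(sphere@antipodeIndex) %/% 2L
  H <- sphere@directions[seq_len(m), , drop = FALSE]

  # precompute nearest hemisphere bin for every valid voxel at once
  vidx <- which(field@valid)
  n <- prod(d)
  V <- cbind(field@axis[vidx], field@axis[vidx + n], field@axis[vidx + 2 * n])
  # z-band window: 4x the equal-area spacing covers the covering radius of
  # the spiral layout with a wide margin; small samplings use a full scan
  band <- if (m <= 1024) m else as.integer(ceiling(4 * sqrt(2 * pi / m) * m) + 2L)
  bin <- if (length(vidx)) .nearestAxisBin(V, H, band) else integer()
  w <- if (weighting == "count") rep(1, length(vidx)) else field@coherence[vidx]

  # block id per valid voxel (NA when outside any full block)
  zyx <- arrayInd(vidx, d) - 1L
  bi <- lapply(1:3, function(a) {
    q <- (zyx[, a] - grid@offset[a]) %/% grid@stride
    r <- (zyx[, a] - grid@offset[a]) %% grid@stride
    ok <- zyx[, a] >= grid@offset[a] & r < B & q < length(org[[a]])
    ifelse(ok, q, NA_integer_)
  })
  nb <- lengths(org)
  out <- vector("list", prod(nb))
  blockId <- bi[[1]] + nb[1] * (bi[[2]] + nb[2] * bi[[3]]) + 1L

  vs <- field@voxelSize
  pos <- 0L
  for (k3 in seq_len(nb[3])) for (k2 in seq_len(nb[2])) for (k1 in seq_len(nb[1])) {
    pos <- pos + 1L
    sel <- which(!is.na(blockId) & blockId == pos)
    bIndex <- c(k1, k2, k3) - 1L
    center <- (c(org[[1]][k1], org[[2]][k2], org[[3]][k3]) + (B - 1) / 2) * vs
    if (length(sel) == 0) {
      out[[pos]] <- new("BlockODF", psi = numeric(nDir), gfa = NA_real_,
                        peaks = matrix(numeric(), 0, 3),
                        peakAmplitudes = numeric(), nValid = 0L,
                        blockIndex = bIndex, centerUm = center, empty = TRUE)
      next
    }
    psi <- numeric(nDir)
    acc <- rowsum(w[sel], bin[sel])
    ids <- as.integer(rownames(acc))
    psi[ids] <- acc[, 1] / 2
    psi[sphere@antipodeIndex[ids]] <- psi[ids]
    psi <- psi / sum(psi)
    pk <- findOdfPeaks(psi, sphere, minSeparationDeg = minSeparationDeg,
                       relAmplitude = relAmplitude)
    out[[pos]] <- new("BlockODF", psi = psi, gfa = gfa(psi), peaks = pk$axes,
                      peakAmplitudes = pk$amplitudes,
                      nValid = length(sel), blockIndex = bIndex,
                      centerUm = center, empty = FALSE)
  }
  out
}

#' Generalized fractional anisotropy of a discrete ODF
#'
#' The standard dMRI dispersion statistic
#' `GFA = sqrt( n * sum((psi - mean(psi))^2) / ((n - 1) * sum(psi^2)) )`,
#' ranging from 0 when all orientations are equally represented to 1 when
#' a single direction carries all the weight.
#'
#' @param psi nonnegative weights over the sphere directions (any positive
#'   sum; normalization cancels).
#' @return GFA in `[0, 1]`.
#' @examples
#' gfa(rep(1, 6500))        # 0: uniform
#' gfa(c(1, rep(0, 6499)))  # 1: single dominant direction
#' @export
gfa <- function(psi) {
  psi <- as.numeric(psi)
  s2 <- sum(psi^2)
  if (!is.finite(s2) || s2 <= 0 || any(psi < 0))
    stop("gfa undefined: psi must be nonnegative with a positive sum")
  n <- length(psi)
  if (sum(psi > 0) == 1L) return(1) # single-support ODF: GFA = 1 analytically
  v <- sum((psi - mean(psi))^2)
  val <- sqrt(n * v / ((n - 1) * s2))
  min(1, max(0, val))
}

#' Detect ODF peaks with a minimum angular separation rule
#'
#' The ODF is lightly smoothed by one step of neighbor-graph averaging
#' (about the bin spacing, suppressing bin noise), local maxima on the
#' graph with amplitude at least `relAmplitude` times the smoothed maximum
#' become candidates, antipodal duplicates are merged into a single axis
#' (the sign-canonical member of each pair), and peaks are selected
#' greedily by amplitude subject to a pairwise axial separation of at
#' least `minSeparationDeg` degrees.
#'
#' @param psi numeric ODF weights, or a [BlockODF-class].
#' @param sphere the [SphereSampling-class] the ODF lives on.
#' @param minSeparationDeg minimum pairwise peak separation (default 45).
#' @param relAmplitude candidate amplitude floor as a fraction of the
#'   smoothed maximum (default 0.3).
#' @param smooth logical; set `FALSE` to skip the neighbor averaging.
#' @return List with `axes` (p x 3 matrix, amplitude-descending) and
#'   `amplitudes`. Empty ODFs give zero peaks.
#' @export
findOdfPeaks <- function(psi, sphere = defaultSphere(), minSeparationDeg = 45,
                         relAmplitude = 0.3, smooth = TRUE) {
  if (is(psi, "BlockODF")) {
    if (psi@empty) return(list(axes = matrix(numeric(), 0, 3),
                               amplitudes = numeric()))
    psi <- psi@psi
  }
  n <- length(psi)
  stopifnot(n == nrow(sphere@directions))
  if (sum(psi) <= 0) return(list(axes = matrix(numeric(), 0, 3),
                                 amplitudes = numeric()))
  ps <- if (smooth) {
    vapply(seq_len(n), function(i)
      (psi[i] + sum(psi[sphere@neighbors[[i]]])) /
        (1 + length(sphere@neighbors[[i]])), 0)
  } else psi
  mx <- max(ps)
  isMax <- vapply(seq_len(n), function(i)
    ps[i] > 0 & all(ps[i] >= ps[sphere@neighbors[[i]]]), NA)
  cand <- which(isMax & ps >= relAmplitude * mx)
  if (length(cand) == 0) cand <- which.max(ps)
  # merge antipodal duplicates: keep one member per pair
  keep <- cand[cand <= sphere@antipodeIndex[cand] |
                 !(sphere@antipodeIndex[cand] %in% cand)]
  keep <- keep[order(ps[keep], decreasing = TRUE)]
  axes <- matrix(numeric(), 0, 3)
  amps <- numeric()
  for (i in keep) {
    v <- sphere@directions[i, ]
    if (nrow(axes) == 0 ||
        all(axialAngleDeg(axes, matrix(v, nrow(axes), 3, byrow = TRUE)) >=
              minSeparationDeg)) {
      axes <- rbind(axes, canonicalizeAxes(v))
      amps <- c(amps, ps[i])
    }
  }
  list(axes = axes, amplitudes = amps)
}
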