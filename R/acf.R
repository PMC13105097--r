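#' @include AllClasses.R utils.R
NULL

#' Orientation dyadic tensor field
#'
#' Converts an orientation field to the per-voxel traceless dyadic tensor
#' `T = v v' - I/3`, the sign-invariant representation of an axial
#' direction suited to correlation analysis (`v` and `-v` give the same
#' tensor). Invalid voxels carry the zero tensor and stay tracked in the
#' mask.
#'
#' @param field an [OrientationField-class].
#' @return A [DyadicField-class].
#' @export
dyadicField <- function(field) {
  stopifnot(is(field, "OrientationField"))
  d <- dim(field@coherence)
  n <- prod(d)
  V <- matrix(field@axis, nrow = n, ncol = 3)
  V[!as.logical(field@valid), ] <- 0
  m <- as.numeric(field@valid)
  comps <- cbind(V[, 1]^2 - m / 3, V[, 2]^2 - m / 3, V[, 3]^2 - m / 3,
                 V[, 1] * V[, 2], V[, 1] * V[, 3], V[, 2] * V[, 3])
  new("DyadicField", comps = array(comps, c(d, 6L)), valid = field@valid,
      voxelSize = field@voxelSize)
}

# Frobenius weights for the 6 stored components (off-diagonals count twice).
.frobW <- c(1, 1, 1, 2, 2, 2)

#' 3D autocorrelation of the orientation tensor field
#'
#' Computes the normalized spatial autocorrelation of the dyadic tensor
#' field over a region: the masked mean tensor is subtracted, each tensor
#' component is correlated by the zero-padded spectral (FFT) method, the
#' components are combined by the Frobenius inner product, and the result
#' is normalized by the valid pair count per lag and by the zero-lag
#' variance, so `C(0) = 1` and `C(lag) = C(-lag)`. Masked voxels are
#' excluded through the pair-count normalization rather than biasing the
#' estimate toward zero. Regions whose masked variance is below `eps` are
#' flagged homogeneous (constant orientation).
#'
#' @param dyadic a [DyadicField-class].
#' @param region optional list `(origin, size)` of 0-based `(z,y,x)` voxel
#'   origin and size selecting a sub-region; `NULL` uses the whole field.
#'   Regions must span >= 32 voxels per axis unless `minSide` is lowered.
#' @param maxLagVox maximum lag per axis in voxels; default half the
#'   region side.
#' @param minValidFraction minimum valid voxel fraction (default 0.1); the
#'   call fails below it, naming the region insufficient.
#' @param eps degeneracy floor on the zero-lag variance.
#' @param minSide minimum region side in voxels.
#' @return An [ACFVolume-class] with lags `-maxLag..maxLag` per axis.
#' @export
acf3d <- function(dyadic, region = NULL, maxLagVox = NULL,
                  minValidFraction = 0.1, eps = 1e-8, minSide = 32L) {
  stopifnot(is(dyadic, "DyadicField"))
  d <- dim(dyadic@valid)
  if (is.null(region)) region <- list(origin = c(0L, 0L, 0L), size = d)
  o <- as.integer(region$origin); sz <- as.integer(region$size)
  if (any(sz < minSide)) stop("region must span at least ", minSide,
                              " voxels per side")
  ix <- lapply(1:3, function(a) o[a] + seq_len(sz[a]))
  mask <- dyadic@valid[ix[[1]], ix[[2]], ix[[3]]] * 1
  vfrac <- mean(mask)
  if (vfrac < minValidFraction)
    stop(sprintf("region insufficient: valid fraction %.3f < %.3f",
                 vfrac, minValidFraction))
  L <- if (is.null(maxLagVox)) sz %/% 2L else rep(as.integer(maxLagVox), 3)
  L <- pmin(L, sz - 1L)
  P <- sz + L # zero padding: no circular wraparound within +-L

  pad <- function(a) {
    out <- array(0, P)
    out[seq_len(sz[1]), seq_len(sz[2]), seq_len(sz[3])] <- a
    out
  }
  Fm <- fft(pad(mask))
  nPairsFull <- Re(fft(Fm * Conj(Fm), inverse = TRUE)) / prod(P)

  num <- array(0, P)
  nv <- sum(mask)
  for (c6 in 1:6) {
    comp <- dyadic@comps[ix[[1]], ix[[2]], ix[[3]], c6]
    mu <- sum(comp * mask) / nv
    g <- (comp - mu) * mask
    Fg <- fft(pad(g))
    num <- num + .frobW[c6] * Re(fft(Fg * Conj(Fg), inverse = TRUE)) / prod(P)
  }
  variance0 <- num[1, 1, 1] / nv

  # centered extraction of lags -L..L
  cen <- function(a) {
    idx <- lapply(1:3, function(ax) c(P[ax] - L[ax] + seq_len(L[ax]), seq_len(L[ax] + 1L)))
    a[idx[[1]], idx[[2]], idx[[3]]]
  }
  nPairs <- round(cen(nPairsFull))
  numC <- cen(num)
  Cn <- array(NA_real_, dim(numC))
  ok <- nPairs > 0.5
  Cn[ok] <- numC[ok] / nPairs[ok]
  homogeneous <- !is.finite(variance0) || variance0 < eps
  if (!homogeneous) Cn <- Cn / variance0
  new("ACFVolume", acf = Cn, lagSpacing = dyadic@voxelSize, nPairs = nPairs,
      variance0 = max(variance0, 0), homogeneous = homogeneous)
}

#' Fiber-frame coordinate axes of an analysis cube
#'
#' Builds the orthonormal frame used to resample the ACF: `e1` is the
#' dominant ODF peak axis; `e2` is the second peak orthogonalized against
#' `e1` when at least two peaks exist, otherwise a deterministic
#' perpendicular (the coordinate axis least aligned with `e1`,
#' orthogonalized); `e3 = e1 x e2`.
#'
#' @param odf a [BlockODF-class] with at least one peak, or a p x 3 matrix
#'   of peak axes.
#' @return 3 x 3 orthonormal matrix with rows `e1`, `e2`, `e3` (`(x,y,z)`
#'   components).
#' @export
blockFrame <- function(odf) {
  peaks <- if (is(odf, "BlockODF")) {
    if (odf@empty) stop("empty ODF: no frame")
    odf@peaks
  } else as.matrix(odf)
  if (nrow(peaks) < 1) stop("ODF has no peaks: no frame")
  e1 <- peaks[1, ] / sqrt(sum(peaks[1, ]^2))
  e2 <- if (nrow(peaks) >= 2) {
    p2 <- peaks[2, ] - sum(peaks[2, ] * e1) * e1
    if (sqrt(sum(p2^2)) < 1e-9) .perpBasis(e1)[1, ] else p2 / sqrt(sum(p2^2))
  } else .perpBasis(e1)[1, ]
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  rbind(e1 = e1, e2 = e2, e3 = e3)
}

# Sample the centered ACF array at physical lag vectors (n x 3, um, (x,y,z)).
.sampleACF <- function(acfv, lagsUm) {
  L <- (dim(acfv@acf) - 1) / 2
  # convert (x,y,z) um to (z,y,x) fractional array indices
  pts <- cbind(lagsUm[, 3] / acfv@lagSpacing[1] + L[1] + 1,
               lagsUm[, 2] / acfv@lagSpacing[2] + L[2] + 1,
               lagsUm[, 1] / acfv@lagSpacing[3] + L[3] + 1)
  Cf <- acfv@acf
  Cf[is.na(Cf)] <- 0
  trilinearSample(Cf, pts)
}

#' Resample an ACF into fiber-frame axial and planar profiles
#'
#' Interpolates the 3D autocorrelation along the fiber-frame axes and
#' averages it over azimuth within the fiber plane `span(e1, e2)` and the
#' transverse plane `span(e2, e3)`, on an `r` grid spaced at the lag
#' spacing from 0 to the window half-length. A 2D slice over the
#' transverse plane is retained for the 2D periodicity spectrum. Opposite
#' lags are averaged (the ACF is symmetric), so all profiles start at
#' exactly `C(0) = 1`.
#'
#' @param acfv an [ACFVolume-class]; homogeneous-flagged ACFs fail.
#' @param frame 3 x 3 frame from [blockFrame()].
#' @param nAzimuth azimuthal samples per ring (default 36).
#' @param rMaxUm profile extent in um; truncated to the available lag
#'   window when larger (default: window half-length).
#' @return An [ACFProfiles-class].
#' @export
radialProfiles <- function(acfv, frame, nAzimuth = 36L, rMaxUm = NULL) {
  stopifnot(is(acfv, "ACFVolume"))
  if (acfv@homogeneous)
    stop("ACF flagged homogeneous (constant orientation field)")
  L <- (dim(acfv@acf) - 1) / 2
  spacing <- mean(acfv@lagSpacing)
  winHalf <- min(L * acfv@lagSpacing)
  if (is.null(rMaxUm)) rMaxUm <- winHalf
  rMaxUm <- min(rMaxUm, winHalf)
  r <- seq(0, rMaxUm, by = spacing)

  axial <- matrix(NA_real_, 3, length(r),
                  dimnames = list(c("e1", "e2", "e3"), NULL))
  for (a in 1:3) {
    u <- frame[a, ]
    vp <- .sampleACF(acfv, outer(r, u))
    vm <- .sampleACF(acfv, outer(-r, u))
    axial[a, ] <- (vp + vm) / 2
  }
  ringAvg <- function(ua, ub) {
    th <- seq(0, pi, length.out = nAzimuth + 1L)[-(nAzimuth + 1L)]
    prof <- rep(0, length(r))
    for (t in th) {
      u <- cos(t) * ua + sin(t) * ub
      prof <- prof + (.sampleACF(acfv, outer(r, u)) +
                        .sampleACF(acfv, outer(-r, u))) / 2
    }
    prof / length(th)
  }
  fiberPlane <- ringAvg(frame[1, ], frame[2, ])
  transverse <- ringAvg(frame[2, ], frame[3, ])

  k <- length(r) - 1L
  g <- seq(-k, k) * spacing
  pts <- as.matrix(expand.grid(u = g, v = g))
  lags <- pts[, 1] %o% frame[2, ] + pts[, 2] %o% frame[3, ]
  t2d <- matrix(.sampleACF(acfv, lags), 2 * k + 1L, 2 * k + 1L)

  new("ACFProfiles", frame = frame, r = r, axial = axial,
      fiberPlaneRadial = fiberPlane, transverseRadial = transverse,
      transverse2d = t2d)
}

#' Fit an exponential decay to an autocorrelation profile
#'
#' Least-squares fit of `C(r) = exp(-r / xi)` on the log scale (slope
#' through the origin, since `C(0) = 1`) over the range from the first
#' nonzero lag to the first lag where the profile drops below `fitFloor`
#' (or the window end). When the profile never decays below `1/e` inside
#' the window, `xi` is capped at the window half-length and flagged; fewer
#' than `minPoints` usable points is a fit failure.
#'
#' @param r lag grid in um (starting at 0).
#' @param C profile values (`C[1] = 1`).
#' @param fitFloor profile floor ending the fit range (default 0.05).
#' @param minPoints minimum usable points (default 5).
#' @return List with `xi` (um), `r2`, `capped`, `fitRange` and `ok`.
#' @examples
#' r <- 0:50
#' fitCorrelationLength(r, exp(-r / 20))$xi  # 20
#' @export
fitCorrelationLength <- function(r, C, fitFloor = 0.05, minPoints = 5L) {
  stopifnot(length(r) == length(C))
  # the profile spans half of the symmetric lag window, so its extent IS
  # the window half-length (the cap value)
  cap <- max(r)
  below <- which(C < fitFloor & r > 0)
  rEnd <- if (length(below)) r[min(below)] else max(r)
  use <- which(r > 0 & r <= rEnd & C >= fitFloor & is.finite(C))
  if (length(use) < minPoints)
    return(list(xi = NA_real_, r2 = NA_real_, capped = FALSE,
                fitRange = c(NA_real_, NA_real_), ok = FALSE))
  x <- r[use]
  y <- log(C[use])
  slope <- sum(x * y) / sum(x^2) # model y = -x/xi through the origin
  xi <- if (slope < 0) -1 / slope else Inf
  ssRes <- sum((y - slope * x)^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else as.numeric(ssRes < 1e-20)
  capped <- FALSE
  if (!is.finite(xi) || min(C[use]) > exp(-1) || xi > cap) {
    # never decays below 1/e inside the window: report the cap, flagged
    xi <- cap
    capped <- TRUE
  }
  list(xi = xi, r2 = max(0, min(1, r2)), capped = capped,
       fitRange = c(min(x), max(x)), ok = TRUE)
}

#' Correlation lengths of an analysis cube along its fiber frame
#'
#' Applies [fitCorrelationLength()] to the three axial profiles of an
#' [ACFProfiles-class] and records the maximum autocorrelation length.
#'
#' @param profiles an [ACFProfiles-class].
#' @param fitFloor,minPoints passed to [fitCorrelationLength()].
#' @return A [CorrelationFit-class].
#' @export
fitBlockCorrelation <- function(profiles, fitFloor = 0.05, minPoints = 5L) {
  stopifnot(is(profiles, "ACFProfiles"))
  fits <- lapply(1:3, function(a)
    fitCorrelationLength(profiles@r, profiles@axial[a, ],
                         fitFloor = fitFloor, minPoints = minPoints))
  xi <- vapply(fits, `[[`, 0, "xi")
  new("CorrelationFit",
      xi = xi,
      r2 = vapply(fits, `[[`, 0, "r2"),
      capped = vapply(fits, `[[`, NA, "capped"),
      fitRange = do.call(rbind, lapply(fits, `[[`, "fitRange")),
      xiMax = maxAutocorrelationLength(xi))
}

#' Maximum autocorrelation length
#'
#' The maximum of the per-axis correlation lengths of a cube — the spatial
#' scale of organization mapped across the tissue. Fails when every axis
#' fit failed.
#'
#' @param fit a [CorrelationFit-class] or a numeric vector of `xi` values
#'   (um), possibly containing `NA` for failed axes.
#' @return Scalar um.
#' @export
maxAutocorrelationLength <- function(fit) {
  xi <- if (is(fit, "CorrelationFit")) fit@xi else as.numeric(fit)
  if (all(is.na(xi))) stop("all axis fits failed: xi_max undefined")
  max(xi, na.rm = TRUE)
}
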