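#' @include AllClasses.R acf.R
NULL

#' Thresholds for the laminar periodicity screen
#'
#' @param minCycles minimum number of full spatial cycles that must fit in
#'   the symmetric profile window (default 1.5).
#' @param snr1d 1D spectral peak SNR threshold (default 3).
#' @param snr2d 2D spectral ring SNR threshold (default 3).
#' @param minModulation minimum oscillation amplitude of the detrended
#'   transverse profile, as a fraction of the zero-lag correlation
#'   (default 0.1). Spectra of autocorrelation profiles carry no white
#'   noise floor (neighboring lags share voxel pairs), so a pure power
#'   ratio cannot distinguish a genuine oscillation from a smooth decay
#'   tail; the depth criterion anchors the screen in correlation units.
#' @param periodBand `[lambda_min, lambda_max]` um searched; the default
#'   lower bound is 10 um and the default (`NA`) upper bound is
#'   `window / minCycles`, the largest period compatible with the cycle
#'   rule. `lambda_min` must be at least twice the lag spacing (Nyquist).
#' @return A [PeriodicityCriteria-class].
#' @export
periodicityCriteria <- function(minCycles = 1.5, snr1d = 3, snr2d = 3,
                                minModulation = 0.1, periodBand = c(10, NA)) {
  new("PeriodicityCriteria", minCycles = as.numeric(minCycles),
      snr1d = as.numeric(snr1d), snr2d = as.numeric(snr2d),
      minModulation = as.numeric(minModulation),
      periodBand = as.numeric(periodBand))
}

# Parabolic refinement of a spectral peak position (log-power).
.parabolicPeak <- function(power, k) {
  if (k <= 1 || k >= length(power)) return(k)
  lp <- log(pmax(power[(k - 1):(k + 1)], .Machine$double.xmin))
  den <- lp[1] - 2 * lp[2] + lp[3]
  if (abs(den) < 1e-300) return(k)
  delta <- 0.5 * (lp[1] - lp[3]) / den
  k + max(-0.5, min(0.5, delta))
}

#' Screen a transverse ACF profile for spatial periodicity
#'
#' Implements the spectral laminar screen. The transverse radial profile is
#' detrended by dividing out its fitted exponential envelope (clamped at a
#' floor so the tail is not blown up), mean-subtracted, Hann-tapered and
#' extended symmetrically to the full lag window (the ACF is even), and its
#' discrete power spectrum is computed. The candidate frequency is the
#' strongest nonzero-frequency peak whose period lies in `periodBand`;
#' `snr1` compares its power to the median power of the other nonzero
#' bins. The number of cycles is the window length times the candidate
#' frequency and must reach `minCycles`. The 2D criterion requires the
#' power spectrum of the transverse 2D ACF slice to show a peak at the
#' matching radial frequency: the ring maximum at the candidate radius
#' must exceed `snr2d` times the median ring maximum at other radii. The
#' period estimate is refined by parabolic interpolation of the spectral
#' peak.
#'
#' @param profiles an [ACFProfiles-class] (transverse profile of length
#'   >= 8 samples).
#' @param criteria a [PeriodicityCriteria-class].
#' @return A partial [LaminarCall-class]: `isLaminar` here means the
#'   periodicity screen passed; the ODF peak-count requirement is added by
#'   [classifyBlock()] (`nPeaks` is `NA` at this stage).
#' @export
detectPeriodicity <- function(profiles, criteria = periodicityCriteria()) {
  stopifnot(is(profiles, "ACFProfiles"))
  validObject(criteria)
  fail <- function(reasons, period = NA_real_, s1 = NA_real_, s2 = NA_real_)
    new("LaminarCall", isLaminar = FALSE, periodUm = period, snr1 = s1,
        snr2 = s2, nPeaks = NA_integer_, reasons = reasons)

  p <- profiles@transverseRadial
  r <- profiles@r
  if (length(p) < 8) return(fail("window"))
  spacing <- r[2] - r[1]
  window <- 2 * max(r) # symmetric lag span of the even-extended profile
  band <- criteria@periodBand
  if (is.na(band[2])) band[2] <- window / criteria@minCycles
  band[1] <- max(band[1], 2 * spacing)

  # detrend: subtract the fitted exponential envelope (keeps the residual
  # in correlation units so modulation depth is meaningful)
  env <- fitCorrelationLength(r, p)
  xi <- if (env$ok && is.finite(env$xi)) env$xi else max(r)
  q <- p - exp(-r / xi)
  q[!is.finite(q)] <- 0
  q <- q - mean(q)
  taper <- 0.5 + 0.5 * cos(pi * r / max(r)) # Hann
  q <- q * taper

  # even extension to the full window; real FFT
  qs <- c(rev(q[-1]), q)
  n <- length(qs)
  taperSum <- 2 * sum(taper) - taper[1]
  pw <- Mod(fft(qs))^2
  nFreqBins <- floor(n / 2)
  kk <- seq_len(nFreqBins) # nonzero-frequency bins
  freq <- kk / (n * spacing)
  period <- 1 / freq
  inBand <- period >= band[1] & period <= band[2]
  if (!any(inBand)) return(fail("band"))
  powK <- pw[kk + 1L]
  kPk <- kk[inBand][which.max(powK[inBand])]
  others <- setdiff(kk, (kPk - 1L):(kPk + 1L))
  noise <- median(powK[others])
  snr1 <- if (powK[kPk] <= 0) 0 else if (noise > 0) powK[kPk] / noise else Inf

  k1Ref <- .parabolicPeak(c(pw[1], powK), kPk + 1L) - 1L # refine on 0..n/2 axis
  fHat <- k1Ref / (n * spacing)

  # oscillation amplitude at the peak in correlation units (C(0) = 1)
  depth <- 2 * sqrt(powK[kPk]) / taperSum

  reasons <- character()
  if (snr1 < criteria@snr1d) reasons <- c(reasons, "snr_1d")
  if (depth < criteria@minModulation) reasons <- c(reasons, "modulation")

  # 2D criterion: ring-maximum spectrum of the transverse plane slice. The
  # 2D spectrum holds a point peak at the laminar frequency, so its ring
  # location is a sharper period estimate than the azimuthally dispersed
  # 1D radial average; the refined frequency is taken from it when it
  # matches the 1D candidate.
  snr2 <- NA_real_
  t2 <- profiles@transverse2d
  if (all(dim(t2) >= 8)) {
    t2[!is.finite(t2)] <- 0
    t2 <- t2 - mean(t2)
    n2 <- nrow(t2)
    h <- 0.5 + 0.5 * cos(pi * seq(-1, 1, length.out = n2))
    t2 <- t2 * (h %o% h)
    P2 <- Mod(fft(t2))^2
    df <- 1 / (n2 * spacing)
    fAxis <- c(0:(floor(n2 / 2)), -(ceiling(n2 / 2) - 1):-1)[seq_len(n2)] * df
    ringId <- round(sqrt(outer(fAxis^2, fAxis^2, `+`)) / df)
    ringMax <- tapply(as.numeric(P2), as.numeric(ringId), max)
    rid <- as.numeric(names(ringMax))
    bandRing <- rid >= 1 & 1 / (rid * df) >= band[1] & 1 / (rid * df) <= band[2]
    if (any(bandRing)) {
      k2 <- rid[bandRing][which.max(ringMax[bandRing])]
      noise2 <- median(ringMax[rid >= 1 & abs(rid - k2) > 1])
      snr2 <- if (noise2 > 0) unname(ringMax[rid == k2]) / noise2 else Inf
      if (snr2 < criteria@snr2d) reasons <- c(reasons, "snr_2d")
      if (abs(k2 * df - fHat) > 2 * df) {
        reasons <- c(reasons, "snr_2d") # no peak at matching radial frequency
      } else if (k2 >= 2 && k2 < max(rid)) {
        lp <- log(pmax(ringMax[rid %in% ((k2 - 1):(k2 + 1))],
                       .Machine$double.xmin))
        den <- lp[1] - 2 * lp[2] + lp[3]
        if (is.finite(den) && abs(den) > 1e-12)
          fHat <- (k2 + max(-0.5, min(0.5, 0.5 * (lp[1] - lp[3]) / den))) * df
        else fHat <- k2 * df
      }
    } else reasons <- c(reasons, "snr_2d")
  } else reasons <- c(reasons, "snr_2d")

  periodHat <- 1 / fHat
  cycles <- window * fHat
  if (cycles < criteria@minCycles) reasons <- c(reasons, "cycles")
  if (periodHat < band[1] || periodHat > band[2])
    reasons <- c(reasons, "band")
  reasons <- unique(reasons)

  if (length(reasons))
    return(fail(reasons, period = periodHat, s1 = snr1, s2 = snr2))
  new("LaminarCall", isLaminar = TRUE, periodUm = periodHat, snr1 = snr1,
      snr2 = snr2, nPeaks = NA_integer_, reasons = character())
}

#' Classify an analysis cube into an architectural motif
#'
#' Conjunction rule: a cube is `"laminar"` exactly when the periodicity
#' screen passed *and* the ODF shows at least two orientation peaks;
#' otherwise it is `"bundled"` when it has a single peak and GFA at or
#' above `gfaBundledFloor`; otherwise `"multi-orientation"`. Empty ODFs are
#' `"masked"`.
#'
#' @param odf a [BlockODF-class].
#' @param call the partial [LaminarCall-class] from [detectPeriodicity()]
#'   (or `NULL` when the ACF was homogeneous/insufficient: treated as no
#'   periodicity).
#' @param gfaBundledFloor GFA floor of the bundled label (default 0.4).
#' @param requireTwoPeaks logical; the two-peak requirement of the laminar
#'   rule (kept as an argument so its effect can be audited — disabling it
#'   can only grow the laminar set).
#' @return List with `motif` (character) and the completed `call`
#'   ([LaminarCall-class] with `nPeaks` filled in).
#' @export
classifyBlock <- function(odf, call, gfaBundledFloor = 0.4,
                          requireTwoPeaks = TRUE) {
  stopifnot(is(odf, "BlockODF"))
  if (odf@empty)
    return(list(motif = "masked",
                call = new("LaminarCall", isLaminar = FALSE,
                           periodUm = NA_real_, snr1 = NA_real_,
                           snr2 = NA_real_, nPeaks = NA_integer_,
                           reasons = "masked")))
  nPeaks <- nrow(odf@peaks)
  if (is.null(call))
    call <- new("LaminarCall", isLaminar = FALSE, periodUm = NA_real_,
                snr1 = NA_real_, snr2 = NA_real_, nPeaks = NA_integer_,
                reasons = "acf")
  call@nPeaks <- as.integer(nPeaks)
  periodic <- isTRUE(call@isLaminar)
  if (periodic && requireTwoPeaks && nPeaks < 2) {
    call@isLaminar <- FALSE
    call@reasons <- unique(c(call@reasons, "n_peaks"))
  }
  motif <- if (isTRUE(call@isLaminar) ||
               (periodic && !requireTwoPeaks)) "laminar"
  else if (nPeaks == 1 && is.finite(odf@gfa) && odf@gfa >= gfaBundledFloor)
    "bundled"
  else "multi-orientation"
  if (motif == "laminar") call@isLaminar <- TRUE
  list(motif = motif, call = call)
}

#' Binary laminar map over the block grid
#'
#' @param calls list of completed [LaminarCall-class] objects in z-major
#'   block order (as produced by the pipeline).
#' @param nBlocks integer length 3, blocks per `(z,y,x)` axis.
#' @param masked optional logical vector marking masked blocks (`NA` in
#'   the map).
#' @return 3D integer array over blocks: 1 = laminar structure present,
#'   0 = absent, `NA` = masked.
#' @export
laminarMap <- function(calls, nBlocks, masked = NULL) {
  v <- vapply(calls, function(cl) as.integer(isTRUE(cl@isLaminar)), 0L)
  if (!is.null(masked)) v[masked] <- NA_integer_
  array(v, nBlocks)
}
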