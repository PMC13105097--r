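#' @include AllClasses.R utils.R
NULL

#' Structure tensor scale parameters
#'
#' Gradient (derivative-of-Gaussian) and window (tensor smoothing) scales
#' in um. Defaults follow the tube model: gradient scale of one fiber
#' radius, window of three radii, so the window averages gradients across a
#' full tube cross-section.
#'
#' @param sigmaGradient derivative-of-Gaussian scale, um (> 0).
#' @param sigmaWindow Gaussian window scale, um (>= `sigmaGradient`).
#' @return A [StructureTensorParams-class].
#' @export
structureTensorParams <- function(sigmaGradient = 1, sigmaWindow = 3) {
  new("StructureTensorParams", sigmaGradient = as.numeric(sigmaGradient),
      sigmaWindow = as.numeric(sigmaWindow))
}

#' Compute the per-voxel 3D structure tensor field
#'
#' Intensity gradients are estimated by derivative-of-Gaussian filtering at
#' `sigmaGradient` (per-axis sigmas derived from the voxel size, so
#' anisotropic voxels are handled), and the gradient outer products are
#' smoothed with a Gaussian window at `sigmaWindow`:
#' `T = G_w * (grad I grad I')`. The result is symmetric positive
#' semidefinite at every voxel (up to roundoff).
#'
#' @param volume 3D `(z,y,x)` intensity array; every axis must span at
#'   least `2 * sigmaWindow / voxelSize` voxels.
#' @param voxelSize voxel size in um, scalar or `(z,y,x)` vector.
#' @param params a [StructureTensorParams-class].
#' @return A [TensorField-class] with components `(xx, yy, zz, xy, xz, yz)`.
#' @seealso [principalOrientation()]
#' @export
computeStructureTensor <- function(volume, voxelSize = 1,
                                   params = structureTensorParams()) {
  validObject(params)
  vs <- voxelSize3(voxelSize)
  d <- dim(volume)
  if (length(d) != 3) stop("volume must be a 3D array")
  if (any(d < 2 * params@sigmaWindow / vs))
    stop("volume too small for sigmaWindow: need >= 2*sigmaWindow/voxelSize voxels per axis")
  sg <- params@sigmaGradient / vs # voxels, (z,y,x)
  sw <- params@sigmaWindow / vs
  if (diff(range(volume)) == 0) # constant volume: exactly zero tensors
    return(new("TensorField", tensors = array(0, c(d, 6L)), voxelSize = vs,
               params = params))
  # gradients in intensity per um: derivative axis 3 -> d/dx etc.
  gx <- convSep3(volume, sg, deriv = 3L) / vs[3]
  gy <- convSep3(volume, sg, deriv = 2L) / vs[2]
  gz <- convSep3(volume, sg, deriv = 1L) / vs[1]
  tens <- array(0, c(d, 6L))
  tens[, , , 1] <- convSep3(gx * gx, sw)
  tens[, , , 2] <- convSep3(gy * gy, sw)
  tens[, , , 3] <- convSep3(gz * gz, sw)
  tens[, , , 4] <- convSep3(gx * gy, sw)
  tens[, , , 5] <- convSep3(gx * gz, sw)
  tens[, , , 6] <- convSep3(gy * gz, sw)
  new("TensorField", tensors = tens, voxelSize = vs, params = params)
}

#' Extract principal fiber orientations from a structure tensor field
#'
#' The fiber axis at a voxel is the eigenvector of the *smallest* structure
#' tensor eigenvalue: along the axis of a bright tubular structure the
#' intensity varies least. Coherence is
#' `(lambda2 - lambda1) / (lambda1 + lambda2 + lambda3)` (eigenvalues
#' ascending), clipped to `[0, 1]`; energy is the tensor trace. Voxels are
#' invalid when their energy falls below `energyFloor` times the volume
#' mean energy (separating labeled tubes from background noise) or when
#' they lie within `ceil(3 * sigmaWindow)` voxels of the volume edge
#' (filter support). Degenerate (near-isotropic) tensors get coherence 0
#' and the conventional axis `e_z`; axes are sign-canonicalized (largest
#' component positive, ties broken z, y, x).
#'
#' @param tensorField a [TensorField-class] from
#'   [computeStructureTensor()].
#' @param energyFloor validity floor as a fraction of the volume mean
#'   energy (default 0.1).
#' @param tieTol relative eigenvalue-gap tolerance declaring a degenerate
#'   tensor.
#' @return An [OrientationField-class].
#' @export
principalOrientation <- function(tensorField, energyFloor = 0.1,
                                 tieTol = 1e-12) {
  stopifnot(is(tensorField, "TensorField"))
  tens <- tensorField@tensors
  d <- dim(tens)[1:3]
  n <- prod(d)
  T6 <- matrix(tens, nrow = n, ncol = 6L)
  e <- .eigSymField(T6)
  ev <- e$eigenvalues
  energy <- ev[, 1] + ev[, 2] + ev[, 3]
  energy[!is.finite(energy)] <- 0
  energy <- pmax(energy, 0)
  gap <- ev[, 2] - ev[, 1]
  coh <- ifelse(energy > 0, gap / energy, 0)
  coh <- pmin(1, pmax(0, coh))
  ax <- e$axis
  tie <- !is.finite(gap) | gap <= tieTol * pmax(energy, .Machine$double.xmin)
  if (any(tie)) {
    ax[tie, 1] <- 0; ax[tie, 2] <- 0; ax[tie, 3] <- 1
    coh[tie] <- 0
  }
  ax <- canonicalizeAxes(ax)

  valid <- energy > 0 & energy >= energyFloor * mean(energy)
  dim(valid) <- d
  # border margin: filter support of the tensor window
  margin <- ceiling(3 * tensorField@params@sigmaWindow / tensorField@voxelSize)
  for (a in 1:3) {
    m <- min(margin[a], floor((d[a] - 1) / 2))
    if (m < 1) next
    idx <- c(seq_len(m), d[a] - seq_len(m) + 1L)
    if (a == 1) valid[idx, , ] <- FALSE
    else if (a == 2) valid[, idx, ] <- FALSE
    else valid[, , idx] <- FALSE
  }
  new("OrientationField",
      axis = array(ax, c(d, 3L)),
      coherence = array(coh, d), energy = array(energy, d),
      valid = valid, voxelSize = tensorField@voxelSize)
}

#' Orientation-coded RGB rendering
#'
#' Maps the axial orientation to color channels
#' `(R, G, B) = (|v . e_ML|, |v . e_DV|, |v . e_AP|)`, scaled by coherence
#' (default) or by a supplied intensity volume; invalid voxels are black.
#' The default anatomical mapping assigns medio-lateral to `x`,
#' dorso-ventral to `y` and antero-posterior to `z`, so a fiber along the
#' medio-lateral axis renders pure red and an antero-posterior fiber pure
#' blue.
#'
#' @param field an [OrientationField-class].
#' @param scaleBy `"coherence"` or `"intensity"`.
#' @param intensity volume used when `scaleBy = "intensity"`, rescaled to
#'   `[0, 1]`.
#' @param anatomicalAxes 3 x 3 matrix, rows = (ML, DV, AP) unit vectors in
#'   `(x,y,z)` components.
#' @return Array `c(dim, 3)` with channels in `[0, 1]`.
#' @export
orientationToRGB <- function(field, scaleBy = c("coherence", "intensity"),
                             intensity = NULL, anatomicalAxes = diag(3)) {
  scaleBy <- match.arg(scaleBy)
  stopifnot(is(field, "OrientationField"))
  d <- dim(field@coherence)
  n <- prod(d)
  V <- matrix(field@axis, nrow = n, ncol = 3)
  amp <- if (scaleBy == "coherence") as.numeric(field@coherence)
  else {
    if (is.null(intensity)) stop("intensity volume required")
    v <- as.numeric(intensity)
    rng <- range(v)
    if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  }
  rgb <- abs(V %*% t(anatomicalAxes)) * amp
  rgb[!as.logical(field@valid), ] <- 0
  rgb <- pmin(1, pmax(0, rgb))
  array(rgb, c(d, 3L))
}
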