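#' @include AllClasses.R
NULL

#' Accessors for fiberarch classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `voxelSize()` returns the `(z,y,x)` voxel size in um, `validMask()` the
#' per-voxel validity mask, `axisArray()` the `c(dim, 3)` array of axial
#' unit vectors, `sphereDirections()` the n x 3 direction matrix,
#' `odfWeights()` the discrete ODF weights and `odfPeaks()` the peak-axis
#' matrix of a [BlockODF-class].
#'
#' @param x an object of the documented class.
#' @return See each accessor's description.
#' @name accessors
#' @aliases voxelSize validMask axisArray sphereDirections odfWeights odfPeaks
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("axisArray", function(x) standardGeneric("axisArray"))
#' @rdname accessors
#' @export
setGeneric("sphereDirections", function(x) standardGeneric("sphereDirections"))
#' @rdname accessors
#' @export
setGeneric("odfWeights", function(x) standardGeneric("odfWeights"))
#' @rdname accessors
#' @export
setGeneric("odfPeaks", function(x) standardGeneric("odfPeaks"))

#' @rdname accessors
setMethod("voxelSize", "OrientationField", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "DyadicField", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "TensorField", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "Phantom", function(x) rep(x@spec@voxelSize, 3))
#' @rdname accessors
setMethod("validMask", "OrientationField", function(x) x@valid)
#' @rdname accessors
setMethod("validMask", "DyadicField", function(x) x@valid)
#' @rdname accessors
setMethod("axisArray", "OrientationField", function(x) x@axis)
#' @rdname accessors
setMethod("sphereDirections", "SphereSampling", function(x) x@directions)
#' @rdname accessors
setMethod("odfWeights", "BlockODF", function(x) x@psi)
#' @rdname accessors
setMethod("odfPeaks", "BlockODF", function(x) x@peaks)

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s motif, %s voxels @ %.3g um\n",
              object@motif, paste(object@shape, collapse = "x"),
              object@voxelSize))
  if (object@motif == "laminar")
    cat(sprintf("  laminar period %.3g um\n", object@laminarPeriod))
  cat(sprintf("  fiber radius %.3g um, jitter %.3g deg, noise sd %.3g\n",
              object@fiberRadius, object@angularJitterDeg, object@noiseSd))
  invisible(NULL)
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom (%s): %s voxels, foreground %.1f%%\n",
              object@spec@motif, paste(dim(object@volume), collapse = "x"),
              100 * mean(object@truthMask)))
  invisible(NULL)
})

setMethod("show", "OrientationField", function(object) {
  cat(sprintf("OrientationField: %s voxels @ (%s) um, %.1f%% valid\n",
              paste(dim(object@coherence), collapse = "x"),
              paste(signif(object@voxelSize, 3), collapse = ", "),
              100 * mean(object@valid)))
  invisible(NULL)
})

setMethod("show", "SphereSampling", function(object) {
  cat(sprintf("SphereSampling: %d directions (antipodally symmetric)\n",
              nrow(object@directions)))
  invisible(NULL)
})

setMethod("show", "BlockODF", function(object) {
  if (object@empty) {
    cat("BlockODF: empty (no valid voxels)\n")
  } else {
    cat(sprintf("BlockODF block (%s): n_valid=%d, GFA=%.3f, %d peak(s)\n",
                paste(object@blockIndex, collapse = ","), object@nValid,
                object@gfa, nrow(object@peaks)))
  }
  invisible(NULL)
})

setMethod("show", "ACFVolume", function(object) {
  cat(sprintf("ACFVolume: lags %s, variance0=%.3g%s\n",
              paste(dim(object@acf), collapse = "x"), object@variance0,
              if (object@homogeneous) " (homogeneous)" else ""))
  invisible(NULL)
})

setMethod("show", "CorrelationFit", function(object) {
  cat(sprintf("CorrelationFit: xi = (%s) um, xi_max = %.3g um\n",
              paste(signif(object@xi, 3), collapse = ", "), object@xiMax))
  invisible(NULL)
})

setMethod("show", "LaminarCall", function(object) {
  cat(sprintf("LaminarCall: %s%s\n",
              if (isTRUE(object@isLaminar)) "laminar" else "not laminar",
              if (isTRUE(object@isLaminar))
                sprintf(", period %.3g um (snr1=%.2f, snr2=%.2f)",
                        object@periodUm, object@snr1, object@snr2)
              else sprintf(" [%s]", paste(object@reasons, collapse = ", "))))
  invisible(NULL)
})

setMethod("show", "PyramidMeta", function(object) {
  cat(sprintf("PyramidMeta: level %d, %.3g um/voxel (tissue scale), %gx expansion\n",
              object@level, object@baseVoxelUm * 2^object@level,
              object@expansionFactor))
  invisible(NULL)
})
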