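#' @include AllClasses.R
NULL

#' Accessors for image-domain objects
#'
#' @param x a [VoxelGrid-class], [IsletMask-class] or [SpheroidModel-class].
#' @return \code{intensities} returns the 3D array; \code{spacing} the
#'   \code{c(dz, dy, dx)} micrometre spacing; \code{maskArray} the logical
#'   3D array; \code{voxelCount} the number of TRUE voxels; \code{isletId}
#'   the integer label; \code{semiAxes} and \code{center} the spheroid
#'   geometry in micrometres; \code{equatorZ} the equatorial plane
#'   z-coordinate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))
#' @rdname accessors
#' @export
setGeneric("isletId", function(x) standardGeneric("isletId"))
#' @rdname accessors
#' @export
setGeneric("semiAxes", function(x) standardGeneric("semiAxes"))
#' @rdname accessors
#' @export
setGeneric("center", function(x) standardGeneric("center"))
#' @rdname accessors
#' @export
setGeneric("equatorZ", function(x) standardGeneric("equatorZ"))

#' @rdname accessors
setMethod("intensities", "VoxelGrid", function(x) x@intensities)
#' @rdname accessors
setMethod("spacing", "VoxelGrid", function(x) x@spacing)
#' @rdname accessors
setMethod("maskArray", "IsletMask", function(x) x@mask)
#' @rdname accessors
setMethod("voxelCount", "IsletMask", function(x) sum(x@mask))
#' @rdname accessors
setMethod("isletId", "IsletMask", function(x) x@isletId)
#' @rdname accessors
setMethod("semiAxes", "SpheroidModel", function(x) x@semiAxes)
#' @rdname accessors
setMethod("center", "SpheroidModel", function(x) x@center)
#' @rdname accessors
setMethod("equatorZ", "SpheroidModel", function(x) x@equatorZ)

#' @describeIn VoxelGrid-class stack dimensions \code{c(nz, ny, nx)}
#' @param x a VoxelGrid
#' @export
setMethod("dim", "VoxelGrid", function(x) dim(x@intensities))

setMethod("show", "VoxelGrid", function(object) {
    d <- dim(object@intensities)
    s <- object@spacing
    cat(sprintf(
        "VoxelGrid: %d x %d x %d voxels (z, y, x), spacing %.3g x %.3g x %.3g um\n",
        d[1], d[2], d[3], s[1], s[2], s[3]))
    cat(sprintf("  field: %.1f x %.1f x %.1f um; intensity range [%.3g, %.3g] a.u.\n",
        (d[1] - 1) * s[1], (d[2] - 1) * s[2], (d[3] - 1) * s[3],
        min(object@intensities), max(object@intensities)))
})

setMethod("show", "IsletMask", function(object) {
    cat(sprintf("IsletMask: islet %d, %d voxels%s\n", object@isletId,
        sum(object@mask),
        if (object@touchesBorder) " (touches lateral border)" else ""))
})

setMethod("show", "SpheroidModel", function(object) {
    cat(sprintf(
        "SpheroidModel: center (z, y, x) = (%.1f, %.1f, %.1f) um\n",
        object@center[1], object@center[2], object@center[3]))
    cat(sprintf("  semi-axes (rz, rxy) = (%.1f, %.1f) um; equator z = %.1f um; rms residual %.2f um (%d boundary voxels)\n",
        object@semiAxes[1], object@semiAxes[2], object@equatorZ,
        object@rmsResidual, object@nBoundary))
})

setMethod("show", "SyntheticConfig", function(object) {
    cat(sprintf(
        "SyntheticConfig: seed %d, stack %s voxels at (%s) um\n",
        object@rngSeed, paste(object@dim, collapse = " x "),
        paste(format(object@spacing), collapse = ", ")))
    cat(sprintf("  islet semi-axes (%s) um, granule fraction %.2f, noise sigma %.2g\n",
        paste(format(object@isletSemiAxes), collapse = ", "),
        object@granuleVolumeFraction, object@noiseSigma))
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf(
        "GroundTruth: total volume %.4g um^3, equatorial %.4g um^3, projected area %.4g um^2, granule fraction %.3f\n",
        object@totalVolume, object@equatorialVolume, object@projectedArea,
        object@granuleVolumeFraction))
})
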