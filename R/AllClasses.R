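#' @import methods
NULL

#' VoxelGrid: a 3D intensity stack with physical voxel spacing
#'
#' The unit of all image processing in this package. Intensities are stored
#' as a 3D numeric array indexed \code{(z, y, x)}; \code{z = 1} is the plane
#' nearest the objective (the shallowest tissue, the "top" of an islet).
#' Spacing is \code{c(dz, dy, dx)} in micrometres per voxel. The physical
#' coordinate of voxel index \code{i} along an axis is \code{(i - 1) * d},
#' i.e. voxel centres sit on a grid starting at 0.
#'
#' @slot intensities 3D numeric array, finite and non-negative, indexed
#'   \code{(z, y, x)}.
#' @slot spacing numeric(3), \code{c(dz, dy, dx)} in micrometres, all
#'   strictly positive and finite.
#'
#' @seealso [VoxelGrid()] for the constructor, [readStack()], [writeStack()]
#' @export
setClass("VoxelGrid",
    representation(intensities = "array", spacing = "numeric"))

setValidity("VoxelGrid", function(object) {
    a <- object@intensities
    s <- object@spacing
    if (length(dim(a)) != 3L)
        return("intensities must be a 3D array indexed (z, y, x)")
    if (any(dim(a) < 2L))
        return("stack must have >= 2 planes along each axis")
    if (!all(is.finite(a)))
        return("intensities must be finite")
    if (any(a < 0))
        return("intensities must be >= 0")
    if (length(s) != 3L || !all(is.finite(s)) || any(s <= 0))
        return("spacing must be 3 strictly positive finite values (dz, dy, dx)")
    TRUE
})

#' Construct a VoxelGrid
#'
#' @param intensities 3D numeric array indexed \code{(z, y, x)}.
#' @param spacing numeric(3): \code{c(dz, dy, dx)} in micrometres/voxel.
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- VoxelGrid(array(0, c(4, 4, 4)), spacing = c(2, 1, 1))
#' dim(g)
#' @export
VoxelGrid <- function(intensities, spacing) {
    new("VoxelGrid", intensities = intensities,
        spacing = as.numeric(spacing))
}

#' IsletMask: one islet's voxels within a VoxelGrid
#'
#' A binary 3D mask congruent with its source stack, identifying the voxels
#' of a single connected islet (26-connectivity).
#'
#' @slot mask logical 3D array, same dimensions as the source stack.
#' @slot isletId integer label (1 = largest islet in the field).
#' @slot touchesBorder logical; TRUE if the component touches the lateral
#'   (y or x) stack border, where it may be clipped.
#' @export
setClass("IsletMask",
    representation(mask = "array", isletId = "integer",
                   touchesBorder = "logical"))

setValidity("IsletMask", function(object) {
    m <- object@mask
    if (length(dim(m)) != 3L || !is.logical(m))
        return("mask must be a logical 3D array")
    if (!any(m))
        return("mask must be non-empty")
    if (length(object@isletId) != 1L || is.na(object@isletId))
        return("isletId must be a single integer")
    TRUE
})

#' Construct an IsletMask
#'
#' @param mask logical 3D array indexed \code{(z, y, x)}.
#' @param isletId integer label.
#' @param touchesBorder logical flag, see [IsletMask-class].
#' @return An [IsletMask-class] object.
#' @export
IsletMask <- function(mask, isletId = 1L, touchesBorder = FALSE) {
    new("IsletMask", mask = mask, isletId = as.integer(isletId),
        touchesBorder = touchesBorder)
}

#' SpheroidModel: fitted axis-aligned spheroid
#'
#' Geometric model of an islet used to locate the equatorial plane. The
#' spheroid is axis-aligned with equal lateral semi-axes (\code{rx = ry}),
#' i.e. a prolate/oblate spheroid about the optical (z) axis. The equator is
#' the horizontal plane through the fitted centre, so \code{equatorZ} equals
#' the centre z by construction.
#'
#' @slot center numeric(3), \code{c(z, y, x)} in micrometres.
#' @slot semiAxes numeric(3), \code{c(rz, ry, rx)} in micrometres with
#'   \code{ry == rx}.
#' @slot equatorZ z-coordinate (micrometres) of the equatorial plane.
#' @slot rmsResidual root-mean-square fit residual in micrometres
#'   (normalized surface residual scaled by the geometric-mean radius).
#' @slot nBoundary number of boundary voxels used in the fit.
#' @export
setClass("SpheroidModel",
    representation(center = "numeric", semiAxes = "numeric",
                   equatorZ = "numeric", rmsResidual = "numeric",
                   nBoundary = "integer"))

setValidity("SpheroidModel", function(object) {
    if (length(object@center) != 3L || !all(is.finite(object@center)))
        return("center must be 3 finite values (z, y, x) in um")
    if (length(object@semiAxes) != 3L || any(object@semiAxes <= 0) ||
        !all(is.finite(object@semiAxes)))
        return("semi-axes must be 3 positive finite values (rz, ry, rx)")
    if (abs(object@semiAxes[2] - object@semiAxes[3]) >
        1e-9 * max(object@semiAxes))
        return("lateral semi-axes must be equal (rx = ry)")
    if (abs(object@equatorZ - object@center[1]) > 1e-9)
        return("equatorZ must equal the center z-coordinate")
    TRUE
})

#' SyntheticConfig: parameters of the backscatter stack simulator
#'
#' Describes one simulated islet: its spheroidal geometry, the insulin
#' granule content that generates the punctate backscatter signal, the
#' optical model (PSF blur, exponential depth attenuation), the scene
#' (background, optional bright iris plane) and the detector noise.
#' Defaults reflect reported beta-cell ultrastructure: granules of
#' 200-400 nm diameter occupying 10-20 percent of the cytoplasmic volume,
#' excluded from nuclei.
#'
#' @slot rngSeed integer seed; every random draw in the generator derives
#'   from it, so output is bit-reproducible.
#' @slot dim integer(3) stack size \code{c(nz, ny, nx)} in voxels.
#' @slot spacing numeric(3) \code{c(dz, dy, dx)} micrometres/voxel.
#' @slot isletSemiAxes numeric(3) \code{c(rz, ry, rx)} micrometres.
#' @slot isletCenter numeric(3) \code{c(z, y, x)} micrometres; \code{NA}
#'   centres the islet in the stack.
#' @slot granuleVolumeFraction fraction of cytoplasmic (non-nuclear) islet
#'   volume occupied by granules, in [0, 0.25].
#' @slot granuleDiameterRange numeric(2) micrometres, default (0.2, 0.4).
#' @slot nucleusFraction fraction of islet volume occupied by nuclei
#'   (granule-free exclusion zones).
#' @slot nucleusDiameter micrometres, default 6.
#' @slot attenuationLength micrometres; 1/e depth decay of granule signal
#'   below the islet top surface.
#' @slot backgroundLevel arbitrary intensity units added everywhere.
#' @slot irisLevel intensity of the bright iris plane; 0 disables it.
#' @slot irisZ z-coordinate (micrometres) of the iris plane; \code{NA}
#'   places it 10 um below the islet bottom.
#' @slot noiseSigma standard deviation of additive Gaussian detector noise.
#' @slot poissonScale photon-counting (shot noise) scale; 0 disables the
#'   Poisson stage.
#' @slot psfSigma numeric(3) \code{c(sz, sy, sx)} micrometres of the
#'   Gaussian point-spread function.
#' @slot scatterGain intensity units per unit granule volume density
#'   (dimensionless density ~0.15 maps to ~0.15 * scatterGain a.u.).
#' @export
setClass("SyntheticConfig",
    representation(rngSeed = "integer", dim = "integer",
                   spacing = "numeric", isletSemiAxes = "numeric",
                   isletCenter = "numeric",
                   granuleVolumeFraction = "numeric",
                   granuleDiameterRange = "numeric",
                   nucleusFraction = "numeric", nucleusDiameter = "numeric",
                   attenuationLength = "numeric",
                   backgroundLevel = "numeric", irisLevel = "numeric",
                   irisZ = "numeric", noiseSigma = "numeric",
                   poissonScale = "numeric", psfSigma = "numeric",
                   scatterGain = "numeric"))

setValidity("SyntheticConfig", function(object) {
    s <- object
    if (length(s@dim) != 3L || any(s@dim < 2L))
        return("dim must be 3 integers >= 2")
    if (any(s@spacing <= 0) || !all(is.finite(s@spacing)))
        return("spacing must be positive and finite")
    if (any(s@isletSemiAxes <= 0))
        return("islet semi-axes must be positive")
    if (s@granuleVolumeFraction < 0 || s@granuleVolumeFraction > 0.25)
        return("granuleVolumeFraction must lie in [0, 0.25]")
    if (length(s@granuleDiameterRange) != 2L ||
        any(s@granuleDiameterRange <= 0) ||
        s@granuleDiameterRange[1] > s@granuleDiameterRange[2])
        return("granuleDiameterRange must be positive with min <= max")
    if (s@nucleusFraction < 0 || s@nucleusFraction > 1)
        return("nucleusFraction must lie in [0, 1]")
    if (s@attenuationLength <= 0)
        return("attenuationLength must be positive")
    if (s@noiseSigma < 0 || s@poissonScale < 0)
        return("noise parameters must be >= 0")
    if (any(s@psfSigma < 0))
        return("psfSigma must be >= 0")
    ctr <- isletCenterUm(s)
    ext <- (s@dim - 1L) * s@spacing
    if (any(ctr - s@isletSemiAxes < 0) || any(ctr + s@isletSemiAxes > ext))
        return("islet does not fit inside the stack bounds")
    TRUE
})

# resolved islet centre in um (NA -> stack centre)
isletCenterUm <- function(config) {
    ctr <- config@isletCenter
    ext <- (config@dim - 1L) * config@spacing
    ifelse(is.na(ctr), ext / 2, ctr)
}

#' Construct a SyntheticConfig
#'
#' All arguments have defaults that simulate a healthy, granule-replete
#' islet (see [SyntheticConfig-class] for the meaning and units of each).
#'
#' @param rngSeed integer seed.
#' @param dim integer(3) stack size \code{c(nz, ny, nx)}.
#' @param spacing numeric(3) micrometres/voxel \code{c(dz, dy, dx)}.
#' @param isletSemiAxes numeric(3) micrometres \code{c(rz, ry, rx)}.
#' @param isletCenter numeric(3) micrometres or NA (stack centre).
#' @param granuleVolumeFraction granule fraction of cytoplasmic volume.
#' @param granuleDiameterRange numeric(2) micrometres.
#' @param nucleusFraction nuclear fraction of islet volume.
#' @param nucleusDiameter micrometres.
#' @param attenuationLength micrometres.
#' @param backgroundLevel,irisLevel,noiseSigma,scatterGain intensity (a.u.).
#' @param irisZ micrometres or NA (auto, below the islet).
#' @param poissonScale shot-noise scale, 0 = off.
#' @param psfSigma numeric(3) micrometres.
#' @return A validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(rngSeed = 7, isletSemiAxes = c(40, 40, 40))
#' @export
syntheticConfig <- function(rngSeed = 1L,
                            dim = c(96L, 96L, 96L),
                            spacing = c(1, 1, 1),
                            isletSemiAxes = c(30, 30, 30),
                            isletCenter = c(NA_real_, NA_real_, NA_real_),
                            granuleVolumeFraction = 0.15,
                            granuleDiameterRange = c(0.2, 0.4),
                            nucleusFraction = 0.10,
                            nucleusDiameter = 6,
                            attenuationLength = 40,
                            backgroundLevel = 10,
                            irisLevel = 0,
                            irisZ = NA_real_,
                            noiseSigma = 5,
                            poissonScale = 0,
                            psfSigma = c(1.5, 0.6, 0.6),
                            scatterGain = 1000) {
    new("SyntheticConfig", rngSeed = as.integer(rngSeed),
        dim = as.integer(dim), spacing = as.numeric(spacing),
        isletSemiAxes = as.numeric(isletSemiAxes),
        isletCenter = as.numeric(isletCenter),
        granuleVolumeFraction = as.numeric(granuleVolumeFraction),
        granuleDiameterRange = as.numeric(granuleDiameterRange),
        nucleusFraction = as.numeric(nucleusFraction),
        nucleusDiameter = as.numeric(nucleusDiameter),
        attenuationLength = as.numeric(attenuationLength),
        backgroundLevel = as.numeric(backgroundLevel),
        irisLevel = as.numeric(irisLevel), irisZ = as.numeric(irisZ),
        noiseSigma = as.numeric(noiseSigma),
        poissonScale = as.numeric(poissonScale),
        psfSigma = as.numeric(psfSigma),
        scatterGain = as.numeric(scatterGain))
}

#' GroundTruth: analytic truth for a simulated islet
#'
#' @slot totalVolume analytic spheroid volume, cubic micrometres.
#' @slot equatorialVolume analytic half-spheroid volume (totalVolume / 2
#'   for the axis-aligned spheroid).
#' @slot projectedArea analytic equatorial ellipse area, square micrometres.
#' @slot granuleVolumeFraction realized nominal granule fraction.
#' @slot semiAxes,center geometry actually rendered, micrometres (z, y, x).
#' @slot growthPerAxis per-axis growth factors when the stack is part of a
#'   series, else NA.
#' @export
setClass("GroundTruth",
    representation(totalVolume = "numeric", equatorialVolume = "numeric",
                   projectedArea = "numeric",
                   granuleVolumeFraction = "numeric",
                   semiAxes = "numeric", center = "numeric",
                   growthPerAxis = "numeric"))

setValidity("GroundTruth", function(object) {
    if (object@totalVolume <= 0 || object@projectedArea <= 0)
        return("ground-truth volumes and areas must be positive")
    if (abs(object@equatorialVolume - object@totalVolume / 2) >
        1e-6 * object@totalVolume)
        return("equatorial volume must be half the total spheroid volume")
    TRUE
})
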