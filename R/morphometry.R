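# Per-islet morphometry: equatorial volume, projected area and the two
# sphere-equivalent diameters. Voxel counts are converted to physical
# units here and only here (volumes um^3, areas um^2, diameters um).

#' Equatorial volume of an islet
#'
#' Volume of the islet from its top surface down to the equator of the
#' fitted spheroid model: the count of mask voxels whose z-centre lies in
#' the closed interval \code{[zTop, equatorZ]}, times the voxel volume
#' \code{dz * dy * dx}. Ties exactly at the equator plane are included
#' (closed at both ends, a sub-voxel convention stated for
#' bit-reproducibility). This half-volume measure is used because depth
#' attenuation makes the lower hemisphere of a backscatter stack
#' unreliable.
#'
#' @param mask an [IsletMask-class].
#' @param spheroid the fitted [SpheroidModel-class] of the same islet.
#' @param spacing numeric(3) \code{c(dz, dy, dx)} micrometres.
#' @return Equatorial volume in cubic micrometres.
#' @export
equatorialVolume <- function(mask, spheroid, spacing) {
    stopifnot(is(mask, "IsletMask"), is(spheroid, "SpheroidModel"))
    zTop <- findTopPlane(mask, spacing)
    zEq <- spheroid@equatorZ
    if (zEq <= zTop)
        stop("degenerate spheroid fit: equator z (", format(zEq),
             " um) not below the islet top (", format(zTop), " um)")
    zc <- axisCoords(dim(mask@mask)[1], spacing[1])
    inSlab <- zc >= zTop & zc <= zEq
    nvox <- sum(mask@mask[inSlab, , ])
    if (nvox == 0L)
        stop("mask has no voxels between the top plane and the equator")
    nvox * prod(spacing)
}

#' Projected area of an islet
#'
#' Area of the union over z of the mask's xy footprints (the binary
#' silhouette in the imaging plane), times the pixel area
#' \code{dy * dx}.
#'
#' @param mask an [IsletMask-class].
#' @param spacing numeric(3) \code{c(dz, dy, dx)} micrometres.
#' @return Projected area in square micrometres.
#' @export
projectedArea <- function(mask, spacing) {
    stopifnot(is(mask, "IsletMask"))
    footprint <- apply(mask@mask, c(2L, 3L), any)
    sum(footprint) * spacing[2] * spacing[3]
}

#' Sphere-equivalent diameters
#'
#' \code{diameterFromVolume} treats the equatorial volume as the
#' half-volume of a sphere: \eqn{2 v_{eq} = \pi d^3 / 6}, so
#' \eqn{d = (12 v_{eq} / \pi)^{1/3}}. \code{diameterFromArea} treats the
#' projected area as a great disc: \eqn{d = 2 \sqrt{a / \pi}}. Agreement
#' of the two diameters indicates a spherical islet.
#'
#' @param veq equatorial volume in cubic micrometres (> 0).
#' @param area projected area in square micrometres (> 0).
#' @return Diameter in micrometres.
#' @examples
#' diameterFromVolume(2 / 3 * pi * 40^3)  # 80
#' diameterFromArea(pi * 40^2)            # 80
#' @export
diameterFromVolume <- function(veq) {
    if (any(!is.finite(veq)) || any(veq <= 0))
        stop("equatorial volume must be positive")
    (12 * veq / pi)^(1 / 3)
}

#' @rdname diameterFromVolume
#' @export
diameterFromArea <- function(area) {
    if (any(!is.finite(area)) || any(area <= 0))
        stop("projected area must be positive")
    2 * sqrt(area / pi)
}

#' Assemble the morphometry record of one islet
#'
#' Computes equatorial volume, projected area and both sphere-equivalent
#' diameters, and records their relative discrepancy as a sphericity
#' index. A discrepancy beyond \code{sphericityTolerance} raises a
#' warning (islet grafts are typically highly spherical, but flattened
#' grafts must still be measurable), never an error.
#'
#' @param grid the source [VoxelGrid-class] (carried for provenance; the
#'   measures derive from the mask and fit).
#' @param mask an [IsletMask-class].
#' @param spheroid the fitted [SpheroidModel-class].
#' @param spacing numeric(3) micrometres; defaults to the grid spacing.
#' @param timepoint character label of the imaging session.
#' @param sphericityTolerance warn when
#'   \code{|d_vol - d_area| / d_area} exceeds this (default 0.15).
#' @return A one-row data.frame: \code{islet_id}, \code{timepoint},
#'   \code{equatorial_volume_um3}, \code{projected_area_um2},
#'   \code{diameter_from_volume_um}, \code{diameter_from_area_um},
#'   \code{sphericity_index}, \code{z_top_um}, \code{equator_z_um}.
#' @export
measureIslet <- function(grid, mask, spheroid, spacing = NULL,
                         timepoint = "t0", sphericityTolerance = 0.15) {
    if (is.null(spacing)) spacing <- grid@spacing
    if (!all(dim(grid@intensities) == dim(mask@mask)))
        stop("grid and mask dimensions differ")
    veq <- equatorialVolume(mask, spheroid, spacing)
    area <- projectedArea(mask, spacing)
    dv <- diameterFromVolume(veq)
    da <- diameterFromArea(area)
    sph <- abs(dv - da) / da
    if (sph > sphericityTolerance)
        warning(sprintf(
            "islet %d: sphere-equivalent diameters differ by %.1f%% (volume %.1f um vs area %.1f um); non-spherical islet?",
            mask@isletId, 100 * sph, dv, da))
    data.frame(islet_id = mask@isletId, timepoint = timepoint,
               equatorial_volume_um3 = veq, projected_area_um2 = area,
               diameter_from_volume_um = dv, diameter_from_area_um = da,
               sphericity_index = sph,
               z_top_um = findTopPlane(mask, spacing),
               equator_z_um = spheroid@equatorZ,
               stringsAsFactors = FALSE)
}

#' Segment, fit and measure every islet in a stack
#'
#' Convenience pipeline: [segmentIslets()], then [fitSpheroid()] and
#' [measureIslet()] per islet. Islets whose spheroid fit fails are
#' dropped with a warning.
#'
#' @param grid a [VoxelGrid-class].
#' @param timepoint session label forwarded to the records.
#' @param ... segmentation parameters passed to [segmentIslets()].
#' @return A list with \code{masks}, \code{spheroids} and \code{records}
#'   (a data.frame with one row per measured islet).
#' @export
analyzeStack <- function(grid, timepoint = "t0", ...) {
    masks <- segmentIslets(grid, ...)
    spheroids <- list()
    rows <- list()
    for (m in masks) {
        sph <- tryCatch(fitSpheroid(m, grid@spacing), error = function(e) {
            warning("islet ", m@isletId, ": spheroid fit failed (",
                    conditionMessage(e), "); islet dropped")
            NULL
        })
        if (is.null(sph)) next
        spheroids[[length(spheroids) + 1L]] <- sph
        rows[[length(rows) + 1L]] <-
            measureIslet(grid, m, sph, timepoint = timepoint)
    }
    list(masks = masks, spheroids = spheroids,
         records = if (length(rows)) do.call(rbind, rows) else
             data.frame())
}
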