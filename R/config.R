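# Config and sidecar serialization: simulation/segmentation parameters in
# YAML or JSON, ground truth as a JSON sidecar, masks as labeled TIFF.

#' Read a SyntheticConfig from YAML or JSON
#'
#' Keys mirror the [syntheticConfig()] arguments (snake_case accepted,
#' e.g. \code{islet_semi_axes}); unknown keys are an error so typos
#' cannot silently fall back to defaults.
#'
#' @param path a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A validated [SyntheticConfig-class].
#' @export
readSyntheticConfig <- function(path) {
    vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    toCamel <- function(x)
        gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
    names(vals) <- toCamel(names(vals))
    known <- names(formals(syntheticConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown config keys: ", paste(bad, collapse = ", "))
    vals <- lapply(vals, unlist)
    do.call(syntheticConfig, vals)
}

#' Write ground truth as a JSON sidecar
#'
#' @param truth a [GroundTruth-class].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
    stopifnot(is(truth, "GroundTruth"))
    jsonlite::write_json(list(
        total_volume_um3 = truth@totalVolume,
        equatorial_volume_um3 = truth@equatorialVolume,
        projected_area_um2 = truth@projectedArea,
        granule_volume_fraction = truth@granuleVolumeFraction,
        semi_axes_um = truth@semiAxes,
        center_um = truth@center,
        growth_per_axis = truth@growthPerAxis),
        path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
}

#' Write a fitted spheroid model as JSON
#'
#' @param spheroid a [SpheroidModel-class].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeSpheroidJson <- function(spheroid, path) {
    stopifnot(is(spheroid, "SpheroidModel"))
    jsonlite::write_json(list(
        center_um = spheroid@center,
        semi_axes_um = spheroid@semiAxes,
        equator_z_um = spheroid@equatorZ,
        rms_residual_um = spheroid@rmsResidual,
        n_boundary_voxels = spheroid@nBoundary),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Export islet masks as a labeled OME-TIFF stack
#'
#' Voxels carry the islet label (1 = largest) and 0 elsewhere, with the
#' source spacing preserved in the OME metadata.
#'
#' @param masks list of [IsletMask-class] from one stack.
#' @param spacing numeric(3) micrometres.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMaskStack <- function(masks, spacing, path) {
    if (length(masks) == 0L) stop("no masks to write")
    lab <- array(0, dim(masks[[1]]@mask))
    for (m in masks) lab[m@mask] <- m@isletId
    writeStack(VoxelGrid(lab, spacing), path)
}
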