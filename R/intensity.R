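# Backscatter intensity index: granule content is read out by averaging
# voxel intensities in a vertical cylinder of 50 um length from the islet
# top towards its centre, with diameter half the islet diameter. The
# cylinder is intersected with the islet mask so cornea/aqueous voxels
# above a tilted surface never contribute.

#' Cylinder-sampled mean backscatter intensity of an islet
#'
#' The sampling cylinder is vertical (along z) through the fitted
#' spheroid centre's (y, x), extends from the islet top plane down by
#' \code{length} micrometres, and has diameter
#' \code{diameterFraction} times the islet's volume-derived
#' sphere-equivalent diameter (the default 0.5 reproduces the
#' "half of the islet diameter" convention). The mean is taken over all
#' voxels whose centres lie inside the cylinder and inside the mask; if
#' the mask's in-cylinder extent is shorter than \code{length}, sampling
#' is truncated at the deepest in-cylinder mask voxel and flagged.
#'
#' @param grid a [VoxelGrid-class].
#' @param mask the islet's [IsletMask-class].
#' @param spheroid the fitted [SpheroidModel-class].
#' @param spacing numeric(3) micrometres; defaults to the grid spacing.
#' @param length cylinder length in micrometres (default 50).
#' @param diameterFraction cylinder diameter as a fraction of the islet
#'   diameter, in (0, 1] (default 0.5).
#' @param timepoint session label.
#' @return A one-row data.frame: \code{islet_id}, \code{timepoint},
#'   \code{mean_cylinder_intensity}, \code{cylinder_length_um},
#'   \code{cylinder_diameter_um}, \code{n_voxels_sampled},
#'   \code{truncated}, and NA placeholders \code{reference_intensity},
#'   \code{normalized_intensity} filled by [referenceNormalize()].
#' @export
cylinderMeanIntensity <- function(grid, mask, spheroid, spacing = NULL,
                                  length = 50, diameterFraction = 0.5,
                                  timepoint = "t0") {
    if (is.null(spacing)) spacing <- grid@spacing
    if (length <= 0) stop("cylinder length must be > 0")
    if (diameterFraction <= 0 || diameterFraction > 1)
        stop("diameterFraction must lie in (0, 1]")
    veq <- equatorialVolume(mask, spheroid, spacing)
    dIslet <- diameterFromVolume(veq)
    cylDiam <- diameterFraction * dIslet
    zTop <- findTopPlane(mask, spacing)
    d <- dim(grid@intensities)
    zc <- axisCoords(d[1], spacing[1])
    yc <- axisCoords(d[2], spacing[2])
    xc <- axisCoords(d[3], spacing[3])
    inR <- outer((yc - spheroid@center[2])^2, (xc - spheroid@center[3])^2,
                 `+`) <= (cylDiam / 2)^2
    inZ <- zc >= zTop & zc <= zTop + length
    cyl <- array(FALSE, d)
    cyl[inZ, , ] <- rep(inR, each = sum(inZ))
    sel <- cyl & mask@mask
    if (!any(sel))
        stop("cylinder intersects no mask voxels (islet ", mask@isletId, ")")
    zSel <- zc[apply(sel, 1L, any)]
    truncated <- (max(zSel) - zTop) < length - spacing[1] / 2
    data.frame(islet_id = mask@isletId, timepoint = timepoint,
               mean_cylinder_intensity = mean(grid@intensities[sel]),
               cylinder_length_um = max(zSel) - zTop,
               cylinder_diameter_um = cylDiam,
               n_voxels_sampled = sum(sel),
               truncated = truncated,
               reference_intensity = NA_real_,
               normalized_intensity = NA_real_,
               stringsAsFactors = FALSE)
}

#' Normalize an intensity record to a reference region
#'
#' Divides the cylinder mean by the mean intensity of a reference region
#' (typically a box on the strongly reflective pigmented iris), making
#' the index invariant to global detector gain between sessions. The
#' region must lie inside the stack and be disjoint from every islet
#' mask.
#'
#' @param record a one-row data.frame from [cylinderMeanIntensity()].
#' @param grid the [VoxelGrid-class] the record was measured on.
#' @param referenceBox numeric(6)
#'   \code{c(zmin, zmax, ymin, ymax, xmin, xmax)} in micrometres.
#' @param masks list of [IsletMask-class] the region must avoid.
#' @return The record with \code{reference_intensity} and
#'   \code{normalized_intensity} filled in.
#' @export
referenceNormalize <- function(record, grid, referenceBox, masks = list()) {
    stopifnot(is(grid, "VoxelGrid"), length(referenceBox) == 6L)
    d <- dim(grid@intensities)
    sp <- grid@spacing
    zc <- axisCoords(d[1], sp[1]); yc <- axisCoords(d[2], sp[2])
    xc <- axisCoords(d[3], sp[3])
    zin <- zc >= referenceBox[1] & zc <= referenceBox[2]
    yin <- yc >= referenceBox[3] & yc <= referenceBox[4]
    xin <- xc >= referenceBox[5] & xc <= referenceBox[6]
    if (!any(zin) || !any(yin) || !any(xin))
        stop("reference region contains no voxels inside the stack")
    box <- array(FALSE, d)
    box[zin, yin, xin] <- TRUE
    for (m in masks)
        if (any(box & m@mask))
            stop("reference region overlaps islet mask ", m@isletId)
    ref <- mean(grid@intensities[box])
    record$reference_intensity <- ref
    record$normalized_intensity <- record$mean_cylinder_intensity / ref
    record
}

#' Compare cylinder intensities between two conditions
#'
#' Pairs intensity records by \code{islet_id} (e.g. fed vs fasted imaging
#' sessions of the same islets) and summarizes the per-islet differences
#' (condition B minus A): cohort mean and standard error, plus a paired
#' two-sided Wilcoxon signed-rank test (and paired t-test) whose p-values
#' are reported raw, never thresholded. When every difference is zero the
#' signed-rank test is undefined and flagged rather than assigned a
#' p-value.
#'
#' @param recordsA,recordsB data.frames of intensity records with columns
#'   \code{islet_id} and \code{mean_cylinder_intensity} (or
#'   \code{normalized_intensity}; see \code{value}).
#' @param value column compared, default \code{"mean_cylinder_intensity"}.
#' @return A list: \code{per_islet} (data.frame of paired values and
#'   differences), \code{mean_difference}, \code{sem_difference},
#'   \code{n}, \code{p_wilcoxon}, \code{p_ttest},
#'   \code{test_undefined} (TRUE when all differences are zero).
#' @export
compareConditions <- function(recordsA, recordsB,
                              value = "mean_cylinder_intensity") {
    need <- c("islet_id", value)
    if (!all(need %in% names(recordsA)) || !all(need %in% names(recordsB)))
        stop("records need columns: ", paste(need, collapse = ", "))
    merged <- merge(recordsA[, need], recordsB[, need],
                    by = "islet_id", suffixes = c("_a", "_b"))
    if (nrow(merged) < nrow(recordsA) || nrow(merged) < nrow(recordsB))
        stop("unpaired islet ids between conditions")
    if (nrow(merged) < 2L)
        stop("need >= 2 paired islets, got ", nrow(merged))
    va <- merged[[paste0(value, "_a")]]
    vb <- merged[[paste0(value, "_b")]]
    diffs <- vb - va
    allZero <- all(diffs == 0)
    pW <- if (allZero) NA_real_ else
        suppressWarnings(stats::wilcox.test(vb, va, paired = TRUE,
                                            exact = NULL)$p.value)
    pT <- if (allZero) NA_real_ else
        stats::t.test(vb, va, paired = TRUE)$p.value
    list(per_islet = data.frame(islet_id = merged$islet_id,
                                value_a = va, value_b = vb,
                                difference = diffs),
         mean_difference = mean(diffs),
         sem_difference = stats::sd(diffs) / sqrt(length(diffs)),
         n = length(diffs),
         p_wilcoxon = pW, p_ttest = pT,
         test_undefined = allZero)
}
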