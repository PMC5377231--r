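# Cohort-level simulation experiments: the longitudinal growth-isotropy
# study (islets imaged at two sessions, pipeline-measured at both) and
# the fed/fasted intensity comparison. These compose the generator and
# the measurement pipeline exactly as a microscope study would.

#' Simulate and measure a longitudinal growth cohort
#'
#' Simulates \code{nIslets} spheroidal islets (radii uniform in
#' \code{radiusRange}), grows each by a per-islet factor drawn uniformly
#' from \code{growthRange} between two imaging sessions (isotropically by
#' default, or anisotropically via \code{growthAxes}), renders both
#' sessions with granule texture and noise, runs the full
#' segment / fit / measure pipeline on every stack, and returns the
#' per-islet one-dimensional growth factors. Islets are assigned
#' round-robin to \code{nBatches} batches (animals).
#'
#' @param seed integer master seed for the whole cohort.
#' @param nIslets number of islets (default 27).
#' @param nBatches number of batches/animals (default 7).
#' @param radiusRange numeric(2) micrometres, session-1 radius range.
#' @param growthRange numeric(2), per-session linear growth factor range.
#' @param growthAxes numeric(3) relative anisotropy multipliers applied
#'   to the drawn factor per axis \code{c(z, y, x)}; \code{c(1, 1, 1)}
#'   (default) is isotropic growth.
#' @param dim,spacing stack geometry (defaults 128^3 voxels at 2 um).
#' @param granuleVolumeFraction granule fraction (default 0.15).
#' @return A list: \code{records} (one [growthFactors()] row per islet,
#'   with a \code{batch} column), \code{truth} (data.frame of true
#'   per-islet radii and growth factors).
#' @seealso [cohortIsotropy()] to summarize the isotropy ratio.
#' @export
simulateGrowthCohort <- function(seed, nIslets = 27L, nBatches = 7L,
                                 radiusRange = c(30, 60),
                                 growthRange = c(1.1, 1.6),
                                 growthAxes = c(1, 1, 1),
                                 dim = c(128L, 128L, 128L),
                                 spacing = c(2, 2, 2),
                                 granuleVolumeFraction = 0.15) {
    set.seed(seed)
    radii <- stats::runif(nIslets, radiusRange[1], radiusRange[2])
    growth <- stats::runif(nIslets, growthRange[1], growthRange[2])
    seeds <- sample.int(2147483646L, nIslets)
    rows <- vector("list", nIslets)
    truth <- vector("list", nIslets)
    for (i in seq_len(nIslets)) {
        g <- growth[i] * growthAxes
        cfg <- syntheticConfig(rngSeed = seeds[i], dim = dim,
                               spacing = spacing,
                               isletSemiAxes = rep(radii[i], 3L),
                               granuleVolumeFraction =
                                   granuleVolumeFraction)
        series <- generateGrowthSeries(cfg, g, nTimepoints = 2L)
        m <- lapply(seq_along(series), function(t)
            measureFirstIslet(series[[t]]$grid, paste0("t", t)))
        rows[[i]] <- cbind(
            growthFactors(i, m[[1]]$equatorial_volume_um3,
                          m[[2]]$equatorial_volume_um3,
                          m[[1]]$projected_area_um2,
                          m[[2]]$projected_area_um2),
            batch = ((i - 1L) %% nBatches) + 1L)
        truth[[i]] <- data.frame(islet_id = i, radius_um = radii[i],
                                 growth_z = g[1], growth_y = g[2],
                                 growth_x = g[3])
    }
    list(records = do.call(rbind, rows), truth = do.call(rbind, truth))
}

# pipeline measurement of the single (largest) islet in a stack
measureFirstIslet <- function(grid, timepoint) {
    masks <- segmentIslets(grid)
    if (length(masks) == 0L)
        stop("pipeline found no islet at ", timepoint)
    sph <- fitSpheroid(masks[[1]], grid@spacing)
    measureIslet(grid, masks[[1]], sph, timepoint = timepoint)
}

#' Simulate and compare a fed/fasted intensity cohort
#'
#' Simulates \code{nPairs} islets each rendered in a granule-replete
#' (fasted) state and a partially degranulated (fed) state with
#' identical geometry and noise, segments the replete stack, and
#' measures the cylinder intensity index on both states through the same
#' mask and spheroid (the same islet imaged on consecutive days).
#' Returns the paired comparison of replete minus degranulated
#' intensities.
#'
#' @param seed integer master seed.
#' @param nPairs number of islets (default 19).
#' @param degranulationFraction granule loss in the fed state
#'   (default 0.3).
#' @param radiusRange numeric(2) micrometres of islet radii.
#' @param dim,spacing stack geometry (defaults 80^3 voxels at 1.5 um).
#' @return A list: \code{comparison} (the [compareConditions()] result,
#'   condition A = fed/degranulated, B = fasted/replete),
#'   \code{fed} and \code{fasted} (per-islet intensity records).
#' @export
simulateFeedingCohort <- function(seed, nPairs = 19L,
                                  degranulationFraction = 0.3,
                                  radiusRange = c(28, 42),
                                  dim = c(80L, 80L, 80L),
                                  spacing = c(1.5, 1.5, 1.5)) {
    set.seed(seed)
    radii <- stats::runif(nPairs, radiusRange[1], radiusRange[2])
    seeds <- sample.int(2147483646L, nPairs)
    fed <- vector("list", nPairs)
    fasted <- vector("list", nPairs)
    for (i in seq_len(nPairs)) {
        cfg <- syntheticConfig(rngSeed = seeds[i], dim = dim,
                               spacing = spacing,
                               isletSemiAxes = rep(radii[i], 3L))
        pair <- generateDegranulationPair(cfg, degranulationFraction)
        masks <- segmentIslets(pair$replete$grid)
        if (length(masks) == 0L) stop("no islet segmented for pair ", i)
        sph <- fitSpheroid(masks[[1]], spacing)
        rec <- function(grid, label)
            cylinderMeanIntensity(grid, masks[[1]], sph,
                                  timepoint = label)
        fasted[[i]] <- rec(pair$replete$grid, "fasted")
        fed[[i]] <- rec(pair$degranulated$grid, "fed")
        fasted[[i]]$islet_id <- fed[[i]]$islet_id <- i
    }
    fed <- do.call(rbind, fed)
    fasted <- do.call(rbind, fasted)
    list(comparison = compareConditions(fed, fasted),
         fed = fed, fasted = fasted)
}
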