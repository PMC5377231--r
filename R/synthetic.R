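# Backscatter stack simulator.
#
# Physical picture: insulin secretory granules (~0.2-0.4 um dense-core
# vesicles, ~10-20% of cytoplasmic volume, absent from nuclei) are the
# dominant scatterers in a beta cell. Each voxel's granule content is a
# Poisson draw at the prescribed number density over the cytoplasmic
# region, which is exactly the voxel-binned marginal of placing granules
# uniformly at random; individual granule volumes enter through the mean
# granule volume E[(pi/6) d^3]. The resulting volume-density field is
# blurred by a Gaussian PSF, attenuated exponentially with depth below
# the islet top surface, superposed on a flat background (plus an
# optional bright iris plane), and degraded by detector noise.
#
# Every random draw derives from rngSeed via fixed sub-seeds (nuclei,
# granule counts, degranulation thinning, noise), so output is
# bit-reproducible and degranulation keeps geometry and noise fixed.

subSeeds <- function(seed) {
    r <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(r)) assign(".Random.seed", r, envir = globalenv()))
    set.seed(seed)
    s <- sample.int(2147483646L, 4L)
    names(s) <- c("nuclei", "granules", "thinning", "noise")
    s
}

meanGranuleVolume <- function(drange) {
    a <- drange[1]; b <- drange[2]
    ed3 <- if (a == b) a^3 else (b^4 - a^4) / (4 * (b - a))
    pi / 6 * ed3
}

# deterministic scene geometry: islet mask, cytoplasm, expected counts
buildScene <- function(config) {
    d <- config@dim; sp <- config@spacing
    ctr <- isletCenterUm(config)
    ax <- config@isletSemiAxes
    islet <- digitizeSpheroidArray(d, sp, ctr, ax)
    nuc <- array(FALSE, d)
    if (config@nucleusFraction > 0) {
        rn <- config@nucleusDiameter / 2
        vIslet <- 4 / 3 * pi * prod(ax)
        nNuc <- round(config@nucleusFraction * vIslet /
                      (4 / 3 * pi * rn^3))
        if (nNuc > 0) {
            centers <- placeNuclei(config, nNuc, ctr, ax, rn)
            nuc <- paintSpheres(d, sp, centers, rn)
        }
    }
    cyto <- islet & !nuc
    lambda <- config@granuleVolumeFraction /
        meanGranuleVolume(config@granuleDiameterRange) * prod(sp)
    list(islet = islet, cyto = cyto, lambdaPerVoxel = lambda,
         center = ctr, semiAxes = ax, zTop = ctr[1] - ax[1])
}

# non-overlapping nucleus centres inside the spheroid (rejection sampling)
placeNuclei <- function(config, n, ctr, ax, rn) {
    set.seed(subSeeds(config@rngSeed)[["nuclei"]])
    inner <- pmax(ax - rn, 0.1 * ax)  # keep nuclei inside the islet
    centers <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(centers) < n && tries < 200L * n) {
        tries <- tries + 1L
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
        p <- ctr + u * inner
        if (nrow(centers) == 0L ||
            min(sqrt(colSums((t(centers) - p)^2))) >= 2 * rn)
            centers <- rbind(centers, p)
    }
    centers
}

# logical array of voxels within radius r of any centre (z, y, x um)
paintSpheres <- function(d, sp, centers, r) {
    out <- array(FALSE, d)
    if (is.null(centers) || nrow(centers) == 0L) return(out)
    for (i in seq_len(nrow(centers))) {
        p <- centers[i, ]
        lo <- pmax(1L, floor((p - r) / sp) + 1L)
        hi <- pmin(d, ceiling((p + r) / sp) + 1L)
        if (any(lo > hi)) next
        z <- (axisCoords(d[1], sp[1])[lo[1]:hi[1]] - p[1])^2
        y <- (axisCoords(d[2], sp[2])[lo[2]:hi[2]] - p[2])^2
        x <- (axisCoords(d[3], sp[3])[lo[3]:hi[3]] - p[3])^2
        q <- outer(outer(z, y, `+`), x, `+`)
        out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
            out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] | (q <= r^2)
    }
    out
}

# render a stack from per-cytoplasm-voxel granule counts
renderStack <- function(config, scene, counts) {
    d <- config@dim; sp <- config@spacing
    dens <- array(0, d)
    dens[scene$cyto] <- counts *
        meanGranuleVolume(config@granuleDiameterRange) / prod(sp)
    sig <- gaussianBlur3d(dens, config@psfSigma, sp)
    zc <- axisCoords(d[1], sp[1])
    atten <- exp(-pmax(0, zc - scene$zTop) / config@attenuationLength)
    sig <- sig * atten  # recycles along z (first dimension)
    img <- config@backgroundLevel + config@scatterGain * sig
    if (config@irisLevel > 0) {
        zIris <- config@irisZ
        if (is.na(zIris)) zIris <- scene$center[1] + scene$semiAxes[1] + 10
        iz <- min(d[1], max(1L, round(zIris / sp[1]) + 1L))
        plane <- img[iz, , ]
        keep <- scene$islet[iz, , ]
        plane[!keep] <- pmax(plane[!keep], config@irisLevel)
        img[iz, , ] <- plane
    }
    set.seed(subSeeds(config@rngSeed)[["noise"]])
    if (config@poissonScale > 0)
        img <- array(stats::rpois(length(img),
                     pmax(img, 0) * config@poissonScale) /
                     config@poissonScale, d)
    if (config@noiseSigma > 0)
        img <- img + stats::rnorm(length(img), 0, config@noiseSigma)
    img <- pmax(img, 0)
    VoxelGrid(array(img, d), spacing = sp)
}

groundTruthFor <- function(config, scene, fraction,
                           growth = c(NA_real_, NA_real_, NA_real_)) {
    v <- 4 / 3 * pi * prod(scene$semiAxes)
    new("GroundTruth", totalVolume = v, equatorialVolume = v / 2,
        projectedArea = pi * scene$semiAxes[2] * scene$semiAxes[3],
        granuleVolumeFraction = fraction, semiAxes = scene$semiAxes,
        center = scene$center, growthPerAxis = as.numeric(growth))
}

drawCounts <- function(config, scene) {
    set.seed(subSeeds(config@rngSeed)[["granules"]])
    n <- sum(scene$cyto)
    if (n == 0L || scene$lambdaPerVoxel == 0) return(integer(max(n, 0L)))
    stats::rpois(n, scene$lambdaPerVoxel)
}

#' Simulate one backscatter stack of a spheroidal islet
#'
#' Generates a [VoxelGrid-class] containing an axis-aligned spheroidal
#' islet filled with punctate granule scatterers (excluded from randomly
#' placed spherical nuclei), PSF-blurred, attenuated exponentially with
#' depth below the islet top, over a flat background with optional bright
#' iris plane and detector noise. Deterministic for a fixed
#' \code{rngSeed}.
#'
#' @param config a [SyntheticConfig-class].
#' @return A list with elements \code{grid} ([VoxelGrid-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @examples
#' out <- generateIsletStack(syntheticConfig(rngSeed = 1,
#'     dim = c(48, 48, 48), isletSemiAxes = c(15, 15, 15)))
#' out$truth
#' @export
generateIsletStack <- function(config) {
    validObject(config)
    scene <- buildScene(config)
    grid <- renderStack(config, scene, drawCounts(config, scene))
    list(grid = grid,
         truth = groundTruthFor(config, scene,
                                config@granuleVolumeFraction))
}

#' Simulate a longitudinal growth series of one islet
#'
#' Renders the same islet at \code{nTimepoints} imaging sessions with
#' semi-axes growing geometrically: timepoint \eqn{t} (0-based) has
#' semi-axes \eqn{(r_z g_z^t, r_y g_y^t, r_x g_x^t)}. Granule volume
#' fraction is held constant; each timepoint is seeded independently but
#' reproducibly from \code{rngSeed}, emulating re-imaging on different
#' days.
#'
#' @param config a [SyntheticConfig-class] describing timepoint 0.
#' @param growthPerAxis numeric(3) per-session growth factors
#'   \code{c(gz, gy, gx)}, all > 0.
#' @param nTimepoints number of sessions (>= 2).
#' @return A list of \code{list(grid, truth)}, one per timepoint.
#' @export
generateGrowthSeries <- function(config, growthPerAxis, nTimepoints = 2L) {
    validObject(config)
    if (any(growthPerAxis <= 0))
        stop("growth factors must be > 0")
    if (nTimepoints < 2L) stop("need >= 2 timepoints")
    r <- get0(".Random.seed", envir = globalenv())
    set.seed(config@rngSeed)
    tseeds <- sample.int(2147483646L, nTimepoints)
    if (!is.null(r)) assign(".Random.seed", r, envir = globalenv())
    lapply(seq_len(nTimepoints) - 1L, function(t) {
        cfg <- config
        cfg@isletSemiAxes <- config@isletSemiAxes * growthPerAxis^t
        cfg@rngSeed <- tseeds[t + 1L]
        validObject(cfg)  # grown islet must still fit the stack
        out <- generateIsletStack(cfg)
        out$truth@growthPerAxis <- as.numeric(growthPerAxis)
        out
    })
}

#' Simulate a granule-replete / degranulated stack pair
#'
#' Models the fasted (replete) versus fed (partially degranulated) states
#' of the same islet: the second stack has identical geometry, nuclei,
#' granule positions and noise, but a uniformly random subset of the
#' granules removed so that its granule volume fraction is
#' \code{(1 - degranulationFraction)} times the original.
#'
#' @param config a [SyntheticConfig-class] for the replete state.
#' @param degranulationFraction fraction of granules removed, in [0, 1].
#' @return A list with elements \code{replete} and \code{degranulated},
#'   each a \code{list(grid, truth)}.
#' @export
generateDegranulationPair <- function(config, degranulationFraction) {
    validObject(config)
    if (degranulationFraction < 0 || degranulationFraction > 1)
        stop("degranulationFraction must lie in [0, 1]")
    scene <- buildScene(config)
    counts <- drawCounts(config, scene)
    set.seed(subSeeds(config@rngSeed)[["thinning"]])
    kept <- stats::rbinom(length(counts), counts,
                          1 - degranulationFraction)
    f0 <- config@granuleVolumeFraction
    list(
        replete = list(grid = renderStack(config, scene, counts),
                       truth = groundTruthFor(config, scene, f0)),
        degranulated = list(
            grid = renderStack(config, scene, kept),
            truth = groundTruthFor(config, scene,
                                   (1 - degranulationFraction) * f0)))
}
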