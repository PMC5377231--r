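# Islet segmentation and spheroid-model fitting.
#
# Backscatter stacks show bright islets on a dark background, so a
# parameter-light, intensity-scale-invariant chain is used: Gaussian
# smoothing, one global Otsu threshold, 26-neighbourhood morphological
# closing, 3D connected components. Depth attenuation corrupts the lower
# hemisphere, so the spheroid model that defines the equatorial plane is
# fitted to the upper-cap boundary only and extrapolated.

#' Segment islets from a backscatter stack
#'
#' Smooths the stack with an isotropic (in micrometres) Gaussian, applies
#' a single global Otsu threshold, closes the binary volume with a
#' 3x3x3 structuring element, labels 26-connected components and keeps
#' those of at least \code{minIsletVolume}. Components are labeled in
#' decreasing volume order; components touching the lateral (y/x) stack
#' border are flagged. Optionally, flat components spanning most of the
#' field (the bright iris plane) are suppressed: any component with
#' z-extent below 3 planes whose xy bounding box covers more than half
#' the field area is dropped.
#'
#' When thresholding finds no credible foreground (foreground and
#' background means separated by less than \code{backgroundMargin}
#' background standard deviations), an empty list is returned with a
#' warning, never an error.
#'
#' @param grid a [VoxelGrid-class].
#' @param smoothingSigma Gaussian smoothing sigma in micrometres
#'   (applied isotropically in physical units; default 2).
#' @param minIsletVolume smallest component kept, cubic micrometres
#'   (default 5000, well below any real islet).
#' @param backgroundMargin minimum foreground/background mean separation
#'   in background standard deviations (default 3).
#' @param suppressIris drop flat field-spanning components (default
#'   TRUE): any component whose robust z-extent (planes holding at least
#'   5 percent of its largest cross-section) is below the larger of 3
#'   planes and the smoothing support \code{3 * smoothingSigma}, with an
#'   xy bounding box covering more than half the field.
#' @return A list of [IsletMask-class], largest first; empty when nothing
#'   segmentable is present.
#' @export
segmentIslets <- function(grid, smoothingSigma = 2, minIsletVolume = 5000,
                          backgroundMargin = 3, suppressIris = TRUE) {
    stopifnot(is(grid, "VoxelGrid"))
    sp <- grid@spacing
    d <- dim(grid@intensities)
    sm <- gaussianBlur3d(grid@intensities, rep(smoothingSigma, 3L), sp)
    th <- otsuThreshold(sm)
    fg <- sm > th
    if (!any(fg) || all(fg)) {
        warning("no islet found: threshold separates nothing")
        return(list())
    }
    muB <- mean(sm[!fg]); sdB <- stats::sd(sm[!fg])
    if (!is.finite(sdB) || sdB == 0) sdB <- .Machine$double.eps
    if (mean(sm[fg]) - muB < backgroundMargin * sdB) {
        warning("no islet found: foreground not separable from background")
        return(list())
    }
    fg <- closing3d(fg)
    cc <- connectedComponents3d(fg)
    voxVol <- prod(sp)
    keep <- which(cc$sizes * voxVol >= minIsletVolume)
    if (length(keep) == 0L) {
        warning("no component reaches minIsletVolume")
        return(list())
    }
    masks <- list()
    for (k in keep[order(cc$sizes[keep], decreasing = TRUE)]) {
        m <- cc$labels == k
        idx <- which(m, arr.ind = TRUE)
        yext <- diff(range(idx[, 2])) + 1L
        xext <- diff(range(idx[, 3])) + 1L
        # robust z-extent: planes holding >= 5% of the component's
        # largest cross-section (closing leaves sub-voxel bumps on a
        # flat iris plane that must not count as extra planes)
        planeAreas <- tabulate(idx[, 1], nbins = d[1])
        zext <- sum(planeAreas >= 0.05 * max(planeAreas))
        # a physically thin plane is thickened by the smoothing kernel,
        # so the flatness cut grows with the smoothing support
        zFlat <- max(3, ceiling(3 * smoothingSigma / sp[1]))
        if (suppressIris && zext < zFlat &&
            yext * xext > 0.5 * d[2] * d[3]) next
        border <- any(idx[, 2] == 1L) || any(idx[, 2] == d[2]) ||
                  any(idx[, 3] == 1L) || any(idx[, 3] == d[3])
        masks[[length(masks) + 1L]] <-
            IsletMask(m, isletId = length(masks) + 1L,
                      touchesBorder = border)
    }
    if (length(masks) == 0L)
        warning("all components suppressed as iris-like")
    masks
}

#' Find the top (shallowest) plane of an islet
#'
#' Returns the physical z-coordinate of the shallowest plane whose mask
#' cross-sectional area reaches at least 5 percent of the mask's maximal
#' cross-sectional area. This robust-top rule prevents isolated noise
#' voxels above the islet from defining its top surface.
#'
#' @param mask an [IsletMask-class].
#' @param spacing numeric(3) \code{c(dz, dy, dx)} micrometres.
#' @param areaFraction robustness threshold (default 0.05).
#' @return z-coordinate of the top plane in micrometres.
#' @export
findTopPlane <- function(mask, spacing, areaFraction = 0.05) {
    stopifnot(is(mask, "IsletMask"))
    areas <- apply(mask@mask, 1L, sum)
    iz <- which(areas >= areaFraction * max(areas))[1]
    (iz - 1) * spacing[1]
}

#' Fit the spheroid model to an islet mask
#'
#' Least-squares fit of an axis-aligned spheroid with equal lateral
#' semi-axes (\code{rx = ry}) to the boundary voxels of the upper portion
#' of the mask. Only boundary voxels at depth up to 60 percent of the
#' mask's z-extent below the top plane are used, because depth
#' attenuation truncates and corrupts the lower hemisphere; the equator
#' is then extrapolated as the horizontal plane through the fitted
#' centre.
#'
#' The spheroid surface
#' \eqn{((x-c_x)^2 + (y-c_y)^2)/a^2 + (z-c_z)^2/c^2 = 1} is linear in a
#' reparameterization, so a direct algebraic least-squares solution seeds
#' a Levenberg-Marquardt refinement of the normalized geometric residual.
#'
#' @param mask an [IsletMask-class] whose visible cap spans >= 5 z-planes.
#' @param spacing numeric(3) \code{c(dz, dy, dx)} micrometres.
#' @param capDepthFraction fraction of the mask z-extent below the top
#'   plane whose boundary voxels enter the fit (default 0.6).
#' @return A [SpheroidModel-class].
#' @export
fitSpheroid <- function(mask, spacing, capDepthFraction = 0.6) {
    stopifnot(is(mask, "IsletMask"))
    m <- mask@mask
    d <- dim(m)
    zplanes <- which(apply(m, 1L, any))
    if (length(zplanes) < 5L)
        stop("mask's visible cap spans fewer than 5 z-planes")
    # boundary voxels: in mask, not interior under 6-connectivity
    interior <- m &
        shiftArray3d(m, 1L, 0L, 0L, TRUE) & shiftArray3d(m, -1L, 0L, 0L, TRUE) &
        shiftArray3d(m, 0L, 1L, 0L, TRUE) & shiftArray3d(m, 0L, -1L, 0L, TRUE) &
        shiftArray3d(m, 0L, 0L, 1L, TRUE) & shiftArray3d(m, 0L, 0L, -1L, TRUE)
    bnd <- which(m & !interior, arr.ind = TRUE)
    zTop <- findTopPlane(mask, spacing)
    zMax <- (max(zplanes) - 1) * spacing[1]
    zCut <- zTop + capDepthFraction * (zMax - zTop)
    pz <- (bnd[, 1] - 1) * spacing[1]
    sel <- pz >= zTop & pz <= zCut
    if (sum(sel) < 9L)
        stop("too few upper-cap boundary voxels (", sum(sel),
             ") for a spheroid fit")
    z <- pz[sel]
    y <- (bnd[sel, 2] - 1) * spacing[2]
    x <- (bnd[sel, 3] - 1) * spacing[3]
    # algebraic seed: x^2 + y^2 = A z^2 + B x + C y + D z + E
    lhs <- x^2 + y^2
    X <- cbind(z2 = z^2, x = x, y = y, z = z, one = 1)
    beta <- stats::lm.fit(X, lhs)$coefficients
    k <- -beta[["z2"]]                 # a^2 / c^2
    cx <- beta[["x"]] / 2
    cy <- beta[["y"]] / 2
    if (k <= 0)
        stop("spheroid fit diverged: non-positive axis ratio (algebraic ",
             "stage), boundary voxels n = ", length(z))
    cz <- beta[["z"]] / (2 * k)
    a2 <- beta[["one"]] + cx^2 + cy^2 + k * cz^2
    if (a2 <= 0)
        stop("spheroid fit diverged: non-positive lateral semi-axis^2 = ",
             format(a2))
    a <- sqrt(a2)
    cc <- sqrt(a2 / k)
    # geometric refinement of normalized surface residuals
    res <- function(p) {
        sqrt(((x - p[1])^2 + (y - p[2])^2) / p[4]^2 +
             (z - p[3])^2 / p[5]^2) - 1
    }
    fit <- minpack.lm::nls.lm(par = c(cx, cy, cz, a, cc), fn = res,
        control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- fit$par
    if (p[4] <= 0 || p[5] <= 0)
        stop("spheroid fit diverged: negative semi-axis after refinement; ",
             "algebraic seed (a, c) = (", format(a), ", ", format(cc), ")")
    rms <- sqrt(mean(res(p)^2)) * (p[4]^2 * p[5])^(1 / 3)
    new("SpheroidModel",
        center = c(p[3], p[2], p[1]),
        semiAxes = c(p[5], p[4], p[4]),
        equatorZ = p[3],
        rmsResidual = rms,
        nBoundary = as.integer(length(z)))
}
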