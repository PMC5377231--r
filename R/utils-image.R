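# Internal 3D image primitives shared by the generator and segmentation.
# Arrays are (z, y, x); physical coordinate of index i is (i - 1) * spacing.

# physical coordinates of voxel centres along one axis
axisCoords <- function(n, d) (seq_len(n) - 1) * d

# 1D truncated, normalized Gaussian kernel; sigma in voxels
gaussKernel1d <- function(sigmaVox) {
    if (sigmaVox < 1e-6) return(1)
    r <- max(1L, ceiling(3 * sigmaVox))
    k <- exp(-(seq(-r, r))^2 / (2 * sigmaVox^2))
    k / sum(k)
}

# banded convolution matrix (zero-padded boundary), n x n
bandMatrix <- function(n, kernel) {
    r <- (length(kernel) - 1L) / 2L
    K <- matrix(0, n, n)
    for (j in seq_along(kernel)) {
        off <- j - r - 1L
        idx <- seq_len(n)
        src <- idx + off
        ok <- src >= 1L & src <= n
        K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + kernel[j]
    }
    K
}

# separable Gaussian blur of a (z, y, x) array; sigma in um, per-axis
gaussianBlur3d <- function(arr, sigmaUm, spacing) {
    d <- dim(arr)
    sigmaVox <- sigmaUm / spacing
    # axis 1 (z)
    if (sigmaVox[1] >= 1e-6) {
        K <- bandMatrix(d[1], gaussKernel1d(sigmaVox[1]))
        arr <- array(K %*% matrix(arr, nrow = d[1]), d)
    }
    # axis 2 (y): bring y first
    if (sigmaVox[2] >= 1e-6) {
        K <- bandMatrix(d[2], gaussKernel1d(sigmaVox[2]))
        a <- aperm(arr, c(2, 1, 3))
        a <- array(K %*% matrix(a, nrow = d[2]), c(d[2], d[1], d[3]))
        arr <- aperm(a, c(2, 1, 3))
    }
    # axis 3 (x)
    if (sigmaVox[3] >= 1e-6) {
        K <- bandMatrix(d[3], gaussKernel1d(sigmaVox[3]))
        a <- aperm(arr, c(3, 1, 2))
        a <- array(K %*% matrix(a, nrow = d[3]), c(d[3], d[1], d[2]))
        arr <- aperm(a, c(2, 3, 1))
    }
    arr
}

# global Otsu threshold of a numeric array.
# EBImage::otsu() operates per 2D frame, so the whole stack is flattened
# into one single-column frame to obtain a single global threshold.
otsuThreshold <- function(x, levels = 4096L) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rng[1])
    img <- EBImage::Image(matrix(as.numeric(x), ncol = 1L))
    EBImage::otsu(img, range = rng, levels = levels)
}

# shift a 3D logical/numeric array by (dz, dy, dx), zero/FALSE fill
shiftArray3d <- function(arr, dz, dy, dx, fill = FALSE) {
    d <- dim(arr)
    out <- array(fill, d)
    zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
    out[zs, ys, xs] <- arr[zs - dz, ys - dy, xs - dx]
    out
}

# 26-neighbourhood (3x3x3 box) dilation / erosion / closing
dilate3d <- function(mask) {
    out <- mask
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        out <- out | shiftArray3d(mask, dz, dy, dx)
    }
    out
}

erode3d <- function(mask) {
    out <- mask
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        out <- out & shiftArray3d(mask, dz, dy, dx, fill = TRUE)
    }
    out
}

closing3d <- function(mask) erode3d(dilate3d(mask))

# Label 26-connected components of a logical 3D array.
# Builds the foreground adjacency graph over the 13 forward neighbour
# offsets and labels components with igraph. Returns an integer array
# (0 = background) and component sizes sorted by label.
connectedComponents3d <- function(mask) {
    d <- dim(mask)
    fg <- which(mask)
    lab <- array(0L, d)
    if (length(fg) == 0L)
        return(list(labels = lab, sizes = integer(0)))
    idmap <- array(0L, d)
    idmap[fg] <- seq_along(fg)
    # voxel (z, y, x) indices of foreground
    z <- ((fg - 1L) %% d[1]) + 1L
    rest <- (fg - 1L) %/% d[1]
    y <- (rest %% d[2]) + 1L
    x <- (rest %/% d[2]) + 1L
    offsets <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
    offsets <- offsets[with(offsets,
        dx > 0 | (dx == 0 & dy > 0) | (dx == 0 & dy == 0 & dz > 0)), ]
    edges <- vector("list", nrow(offsets))
    for (i in seq_len(nrow(offsets))) {
        dz <- offsets$dz[i]; dy <- offsets$dy[i]; dx <- offsets$dx[i]
        z2 <- z + dz; y2 <- y + dy; x2 <- x + dx
        ok <- z2 >= 1L & z2 <= d[1] & y2 >= 1L & y2 <= d[2] &
              x2 >= 1L & x2 <= d[3]
        if (!any(ok)) next
        nb <- idmap[cbind(z2[ok], y2[ok], x2[ok])]
        hit <- nb > 0L
        if (!any(hit)) next
        edges[[i]] <- cbind(idmap[fg[ok]][hit], nb[hit])
    }
    edges <- do.call(rbind, edges)
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
    if (!is.null(edges) && nrow(edges) > 0L)
        g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)
    lab[fg] <- comp$membership
    list(labels = lab, sizes = as.integer(comp$csize))
}

# logical array of voxels whose centres lie inside an axis-aligned spheroid
# centre/semiAxes in um (z, y, x)
digitizeSpheroidArray <- function(dim, spacing, center, semiAxes) {
    z <- (axisCoords(dim[1], spacing[1]) - center[1]) / semiAxes[1]
    y <- (axisCoords(dim[2], spacing[2]) - center[2]) / semiAxes[2]
    x <- (axisCoords(dim[3], spacing[3]) - center[3]) / semiAxes[3]
    q <- outer(outer(z^2, y^2, `+`), x^2, `+`)
    q <= 1
}

#' Digitize an axis-aligned spheroid into an IsletMask
#'
#' Voxel-centre sampling of the spheroid
#' \eqn{((z-cz)/rz)^2 + ((y-cy)/ry)^2 + ((x-cx)/rx)^2 \le 1} on the grid of
#' a stack of the given dimensions and spacing. Used as the analytic oracle
#' in morphometry validation and available for constructing test masks.
#'
#' @param dim integer(3) \code{c(nz, ny, nx)}.
#' @param spacing numeric(3) micrometres/voxel.
#' @param center numeric(3) micrometres \code{c(z, y, x)}.
#' @param semiAxes numeric(3) micrometres \code{c(rz, ry, rx)}.
#' @param isletId integer label for the resulting mask.
#' @return An [IsletMask-class].
#' @examples
#' m <- digitizeSpheroid(c(64, 64, 64), c(1, 1, 1), c(31.5, 31.5, 31.5),
#'                       c(20, 20, 20))
#' voxelCount(m)
#' @export
digitizeSpheroid <- function(dim, spacing, center, semiAxes, isletId = 1L) {
    IsletMask(digitizeSpheroidArray(as.integer(dim), spacing, center,
                                    semiAxes), isletId = isletId)
}
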