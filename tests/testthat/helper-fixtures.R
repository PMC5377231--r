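# Fixtures built in code; no binary files ship with the package.

# small, fast islet simulation used across tests
smallConfig <- function(seed = 1L, r = 20, dim = c(64L, 64L, 64L),
                        spacing = c(1, 1, 1), ...) {
    syntheticConfig(rngSeed = seed, dim = dim, spacing = spacing,
                    isletSemiAxes = rep(r, 3L), ...)
}

# a perfect spheroid model built from known geometry (z, y, x um)
truthSpheroid <- function(center, semiAxes) {
    new("SpheroidModel", center = center,
        semiAxes = c(semiAxes[1], semiAxes[2], semiAxes[2]),
        equatorZ = center[1], rmsResidual = 0, nBoundary = 0L)
}

# logical upper-half selector (z-coordinate <= zc) for an array
upperHalf <- function(dim, spacing, zc) {
    z <- (seq_len(dim[1]) - 1) * spacing[1] <= zc
    array(rep(z, prod(dim[2:3])), dim)
}

diceCoefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# full pipeline on a single-islet stack, returning the morphometry row
measureFirstIsletForTest <- function(grid) {
    masks <- segmentIslets(grid)
    stopifnot(length(masks) >= 1L)
    sph <- fitSpheroid(masks[[1]], spacing(grid))
    measureIslet(grid, masks[[1]], sph)
}

# full pipeline, returning the cylinder intensity index
measureCylinderForTest <- function(grid) {
    masks <- segmentIslets(grid)
    stopifnot(length(masks) >= 1L)
    sph <- fitSpheroid(masks[[1]], spacing(grid))
    cylinderMeanIntensity(grid, masks[[1]], sph)$mean_cylinder_intensity
}

# three-row morphometry table for I/O tests
sampleRecords <- function() {
    do.call(rbind, lapply(1:3, function(i)
        data.frame(islet_id = i, timepoint = "t0",
                   equatorial_volume_um3 = exp(i) * 1e4,
                   projected_area_um2 = sqrt(2) * i * 1e3,
                   diameter_from_volume_um = 40 + i / 3,
                   diameter_from_area_um = 41 + i / 7,
                   stringsAsFactors = FALSE)))
}
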