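test_that("a single synthetic islet segments into one accurate mask", {
    cfg <- smallConfig(seed = 21, r = 20)
    out <- generateIsletStack(cfg)
    masks <- segmentIslets(out$grid)
    expect_length(masks, 1L)
    truthMask <- maskArray(digitizeSpheroid(cfg@dim, cfg@spacing,
                                            rep(31.5, 3), rep(20, 3)))
    up <- upperHalf(cfg@dim, cfg@spacing, 31.5)
    expect_gt(diceCoefficient(maskArray(masks[[1]]) & up,
                              truthMask & up), 0.9)
})

test_that("upper-hemisphere accuracy holds across granule fractions", {
    for (frac in c(0.10, 0.15, 0.20)) {
        cfg <- smallConfig(seed = 31, r = 20,
                           granuleVolumeFraction = frac)
        out <- generateIsletStack(cfg)
        masks <- segmentIslets(out$grid)
        expect_length(masks, 1L)
        truthMask <- maskArray(digitizeSpheroid(cfg@dim, cfg@spacing,
                                                rep(31.5, 3), rep(20, 3)))
        up <- upperHalf(cfg@dim, cfg@spacing, 31.5)
        expect_gt(diceCoefficient(maskArray(masks[[1]]) & up,
                                  truthMask & up), 0.9)
    }
})

test_that("a pure background stack yields an empty list with a warning", {
    set.seed(99)
    g <- VoxelGrid(array(pmax(rnorm(48^3, 10, 5), 0), rep(48L, 3L)),
                   c(1, 1, 1))
    expect_warning(masks <- segmentIslets(g), "no islet|no component")
    expect_length(masks, 0L)
})

test_that("two well-separated islets segment separately, largest first", {
    mk <- function(seed, r, cz) {
        cfg <- syntheticConfig(rngSeed = seed, dim = c(64L, 64L, 128L),
                               spacing = c(1, 1, 1),
                               isletSemiAxes = rep(r, 3L),
                               isletCenter = c(31.5, 31.5, cz))
        generateIsletStack(cfg)$grid
    }
    g1 <- mk(1, 14, 32)
    g2 <- mk(2, 20, 96)
    merged <- VoxelGrid(pmax(intensities(g1), intensities(g2)), c(1, 1, 1))
    masks <- segmentIslets(merged)
    expect_length(masks, 2L)
    expect_gt(voxelCount(masks[[1]]), voxelCount(masks[[2]]))
    expect_equal(isletId(masks[[1]]), 1L)
    # each mask sits in the correct half of the field
    xs1 <- which(apply(maskArray(masks[[1]]), 3L, any))
    expect_gt(mean(xs1), 64)  # larger islet centred at x = 96
})

test_that("segmentation is invariant to global intensity scaling", {
    cfg <- smallConfig(seed = 13, r = 18)
    g <- generateIsletStack(cfg)$grid
    m1 <- segmentIslets(g)
    m2 <- segmentIslets(VoxelGrid(intensities(g) * 37.5, spacing(g)))
    expect_identical(maskArray(m1[[1]]), maskArray(m2[[1]]))
})

test_that("the iris plane is suppressed, not segmented as an islet", {
    cfg <- smallConfig(seed = 17, r = 15, irisLevel = 400)
    out <- generateIsletStack(cfg)
    masks <- segmentIslets(out$grid)
    expect_length(masks, 1L)
    zext <- diff(range(which(apply(maskArray(masks[[1]]), 1L, any))))
    expect_gt(zext, 3L)  # the surviving component is the islet
})

test_that("findTopPlane uses the robust 5% area rule", {
    dz <- 2
    m <- array(FALSE, c(60, 40, 40))
    for (iz in 11:51)  # growing cross-section from plane 11
        m[iz, 1:min(40, iz - 9), 1:40] <- TRUE
    expect_equal(findTopPlane(IsletMask(m), c(dz, 1, 1)), 10 * dz)

    stray <- m
    stray[3, 20, 20] <- TRUE  # single noise voxel far above the body
    expect_equal(findTopPlane(IsletMask(stray), c(dz, 1, 1)), 10 * dz)

    # brute-force oracle: first plane with area >= 5% of max area
    areas <- apply(stray, 1, sum)
    expect_equal(findTopPlane(IsletMask(stray), c(dz, 1, 1)),
                 (which(areas >= 0.05 * max(areas))[1] - 1) * dz)

    sphere <- digitizeSpheroid(c(96L, 96L, 96L), c(1, 1, 1),
                               rep(47.5, 3), rep(40, 3))
    expect_lt(abs(findTopPlane(sphere, c(1, 1, 1)) - (47.5 - 40)), 2)
})

test_that("fitSpheroid recovers digitized geometry", {
    # exact sphere r = 40
    m <- digitizeSpheroid(c(96L, 96L, 96L), c(1, 1, 1), rep(47.5, 3),
                          rep(40, 3))
    fit <- fitSpheroid(m, c(1, 1, 1))
    expect_lt(max(abs(semiAxes(fit) - 40)) / 40, 0.02)
    expect_lt(abs(equatorZ(fit) - 47.5), 1)

    # oblate spheroid rz = 30, rxy = 45
    mo <- digitizeSpheroid(c(96L, 112L, 112L), c(1, 1, 1),
                           c(47.5, 55.5, 55.5), c(30, 45, 45))
    fo <- fitSpheroid(mo, c(1, 1, 1))
    expect_lt(abs(semiAxes(fo)[1] - 30) / 30, 0.05)
    expect_lt(abs(semiAxes(fo)[2] - 45) / 45, 0.05)

    # hemisphere-only mask, as depth attenuation produces
    hemi <- maskArray(m)
    hemi[(0:95) > 47.5, , ] <- FALSE
    fh <- fitSpheroid(IsletMask(hemi), c(1, 1, 1))
    expect_lt(abs(equatorZ(fh) - 47.5), 2)
})

test_that("fitSpheroid shifts exactly with whole-voxel translations", {
    m <- digitizeSpheroid(c(80L, 80L, 80L), c(1, 1, 1), rep(33.5, 3),
                          rep(22, 3))
    f0 <- fitSpheroid(m, c(1, 1, 1))
    arr <- maskArray(m)
    shifted <- array(FALSE, dim(arr))
    shifted[1:70 + 4, 1:70 + 6, 1:70 + 3] <- arr[1:70, 1:70, 1:70]
    f1 <- fitSpheroid(IsletMask(shifted), c(1, 1, 1))
    expect_equal(center(f1), center(f0) + c(4, 6, 3), tolerance = 1e-6)
})

test_that("degenerate masks are rejected with diagnostics", {
    flat <- array(FALSE, c(16, 16, 16))
    flat[4:6, 4:12, 4:12] <- TRUE
    expect_error(fitSpheroid(IsletMask(flat), c(1, 1, 1)),
                 "fewer than 5 z-planes")
})
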