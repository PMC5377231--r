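test_that("cylinder mean is exact on a constant-intensity islet", {
    n <- 64L
    ctr <- rep(31.5, 3)
    m <- digitizeSpheroid(rep(n, 3L), c(1, 1, 1), ctr, rep(20, 3))
    img <- array(1, rep(n, 3L))
    img[maskArray(m)] <- 7.25
    g <- VoxelGrid(img, c(1, 1, 1))
    sph <- truthSpheroid(ctr, c(20, 20))
    rec <- cylinderMeanIntensity(g, m, sph)
    expect_identical(rec$mean_cylinder_intensity, 7.25)
    expect_true(rec$truncated)  # 20 um radius cannot host 50 um of depth
    expect_gt(rec$n_voxels_sampled, 0)
})

test_that("cylinder diameter is half the islet diameter and matches an oracle", {
    n <- 96L
    ctr <- rep(47.5, 3)
    m <- digitizeSpheroid(rep(n, 3L), c(1, 1, 1), ctr, rep(40, 3))
    sph <- truthSpheroid(ctr, c(40, 40))
    set.seed(1)
    g <- VoxelGrid(array(runif(n^3, 0, 100), rep(n, 3L)), c(1, 1, 1))
    rec <- cylinderMeanIntensity(g, m, sph)
    veq <- equatorialVolume(m, sph, c(1, 1, 1))
    expect_equal(rec$cylinder_diameter_um, 0.5 * diameterFromVolume(veq))
    expect_lt(abs(rec$cylinder_diameter_um - 40) / 40, 0.01)

    # brute-force oracle: average over explicitly enumerated voxels
    zTop <- findTopPlane(m, c(1, 1, 1))
    sel <- which(maskArray(m), arr.ind = TRUE)
    z <- sel[, 1] - 1; y <- sel[, 2] - 1; x <- sel[, 3] - 1
    inCyl <- z >= zTop & z <= zTop + 50 &
        (y - ctr[2])^2 + (x - ctr[3])^2 <= (rec$cylinder_diameter_um / 2)^2
    oracle <- mean(intensities(g)[sel[inCyl, , drop = FALSE]])
    expect_equal(rec$mean_cylinder_intensity, oracle)
})

test_that("voxels outside the mask never contribute to the cylinder", {
    n <- 48L
    ctr <- rep(23.5, 3)
    m <- digitizeSpheroid(rep(n, 3L), c(1, 1, 1), ctr, rep(14, 3))
    img <- array(1, rep(n, 3L))
    img[maskArray(m)] <- 5
    g1 <- VoxelGrid(img, c(1, 1, 1))
    sph <- truthSpheroid(ctr, c(14, 14))
    r1 <- cylinderMeanIntensity(g1, m, sph)
    # plant an extreme voxel inside the cylinder bounding box, above the
    # islet surface (outside the mask)
    img[3, 24, 24] <- 1e6
    r2 <- cylinderMeanIntensity(VoxelGrid(img, c(1, 1, 1)), m, sph)
    expect_identical(r2$mean_cylinder_intensity,
                     r1$mean_cylinder_intensity)
})

test_that("degranulation lowers the cylinder intensity index", {
    cfg <- smallConfig(seed = 23, r = 20)
    pair <- generateDegranulationPair(cfg, 0.5)
    masks <- segmentIslets(pair$replete$grid)
    sph <- fitSpheroid(masks[[1]], c(1, 1, 1))
    full <- cylinderMeanIntensity(pair$replete$grid, masks[[1]], sph)
    thin <- cylinderMeanIntensity(pair$degranulated$grid, masks[[1]], sph)
    expect_lt(thin$mean_cylinder_intensity, full$mean_cylinder_intensity)
})

test_that("cylinder intensity rises monotonically with granule fraction", {
    vals <- vapply(c(0.05, 0.10, 0.15, 0.20), function(frac) {
        cfg <- smallConfig(seed = 29, r = 20,
                           granuleVolumeFraction = frac)
        out <- generateIsletStack(cfg)
        masks <- segmentIslets(out$grid)
        sph <- fitSpheroid(masks[[1]], c(1, 1, 1))
        cylinderMeanIntensity(out$grid, masks[[1]],
                              sph)$mean_cylinder_intensity
    }, numeric(1))
    expect_true(all(diff(vals) > 0))
})

test_that("reference normalization is a ratio and gain-invariant", {
    n <- 48L
    ctr <- rep(23.5, 3)
    m <- digitizeSpheroid(rep(n, 3L), c(1, 1, 1), ctr, rep(14, 3))
    img <- array(0.5, rep(n, 3L))
    img[maskArray(m)] <- 4
    img[44:47, , ] <- 8  # constant reference slab (e.g. iris), 2x cylinder
    g <- VoxelGrid(img, c(1, 1, 1))
    sph <- truthSpheroid(ctr, c(14, 14))
    rec <- cylinderMeanIntensity(g, m, sph)
    box <- c(43, 46, 0, 47, 0, 47)
    norm1 <- referenceNormalize(rec, g, box, list(m))
    expect_equal(norm1$normalized_intensity, 0.5)

    g2 <- VoxelGrid(intensities(g) * 12.7, c(1, 1, 1))
    rec2 <- cylinderMeanIntensity(g2, m, sph)
    norm2 <- referenceNormalize(rec2, g2, box, list(m))
    expect_equal(norm2$normalized_intensity, norm1$normalized_intensity,
                 tolerance = 1e-12)

    overlapping <- c(20, 30, 20, 30, 20, 30)
    expect_error(referenceNormalize(rec, g, overlapping, list(m)),
                 "overlaps")
    expect_error(referenceNormalize(rec, g, c(100, 110, 0, 10, 0, 10)),
                 "no voxels")
})

test_that("condition comparison pairs by islet and reports raw p-values", {
    recs <- data.frame(islet_id = 1:5,
                       mean_cylinder_intensity = c(10, 12, 9, 14, 11))
    same <- compareConditions(recs, recs)
    expect_equal(same$mean_difference, 0)
    expect_true(same$test_undefined)
    expect_true(is.na(same$p_wilcoxon))

    up <- recs
    up$mean_cylinder_intensity <- recs$mean_cylinder_intensity + c(1, 2, 1, 3, 2)
    cmp <- compareConditions(recs, up)
    expect_equal(cmp$mean_difference, 1.8)
    expect_equal(cmp$n, 5L)
    expect_false(is.na(cmp$p_wilcoxon))
    expect_false(is.na(cmp$p_ttest))

    expect_error(compareConditions(recs[1, ], up[1, ]), ">= 2")
    bad <- up; bad$islet_id <- 6:10
    expect_error(compareConditions(recs, bad), "unpaired")
})
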